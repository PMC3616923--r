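## Domain data model and readers/writers. All internal coordinates are
## 0-based half-open; GFF3/VCF-style 1-based coordinates are converted at
## the boundary, never carried internally.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse-complement a DNA string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return reverse complement, same alphabet.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Construct an annotated genome
#'
#' @param sequences named character vector, chromosome id -> DNA sequence.
#' @param genes data.frame with columns gene_id, chrom_id, strand ("+"/"-"),
#'   start, end (0-based half-open), coding (logical).
#' @param cds named list (by gene_id) of two-column integer matrices
#'   (start, end), 0-based half-open, sorted, non-overlapping.
#' @return an `AnnotatedGenome` object. `order_index` is (re)assigned per
#'   chromosome by start position, 0-based.
#' @export
annotated_genome <- function(sequences, genes, cds) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (any(!nzchar(sequences))) stop("empty chromosome sequence")
  bad <- setdiff(genes$chrom_id, names(sequences))
  if (length(bad) > 0) {
    stop("gene refers to unknown chromosome: ", paste(bad, collapse = ", "))
  }
  if (is.null(genes$deleted)) genes$deleted <- FALSE
  genes <- assign_order_index(genes)
  g <- structure(
    list(sequences = sequences, genes = genes, cds = cds),
    class = "AnnotatedGenome"
  )
  g
}

## order_index: consecutive 0-based rank along each chromosome by start
## (deleted genes carry NA).
assign_order_index <- function(genes) {
  genes[["order_index"]] <- rep(NA_integer_, nrow(genes))
  for (ch in unique(genes$chrom_id)) {
    i <- which(genes$chrom_id == ch & !genes$deleted)
    genes$order_index[i][order(genes$start[i])] <- seq_along(i) - 1L
  }
  genes
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat(sprintf(
    "AnnotatedGenome: %d chromosome(s) (%.0f bp), %d gene(s), %d coding\n",
    length(x$sequences), sum(nchar(x$sequences)), nrow(x$genes),
    sum(x$genes$coding)
  ))
  invisible(x)
}

#' Read a genome from FASTA and GFF3
#'
#' Gene/mRNA/CDS features are read; only ID/Parent attributes are used.
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open.
#' Genes whose concatenated CDS length is not divisible by 3 are flagged
#' non-coding with a warning.
#'
#' @param fasta_path path to a FASTA file of chromosome sequences.
#' @param gff3_path path to a GFF3 file with gene/mRNA/CDS features.
#' @return an [annotated_genome()].
#' @export
read_genome <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  sequences <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  gff <- rtracklayer::readGFF(gff3_path)
  gff <- as.data.frame(gff)
  bad <- setdiff(unique(as.character(gff$seqid)), names(sequences))
  if (length(bad) > 0) {
    stop("GFF3 refers to unknown chromosome: ", paste(bad, collapse = ", "))
  }
  gn <- gff[gff$type == "gene", ]
  mr <- gff[gff$type == "mRNA", ]
  cd <- gff[gff$type == "CDS", ]
  mrna_gene <- setNames(as.character(mr$Parent), as.character(mr$ID))
  genes <- data.frame(
    gene_id = as.character(gn$ID),
    chrom_id = as.character(gn$seqid),
    strand = as.character(gn$strand),
    start = gn$start - 1L,
    end = gn$end,
    coding = FALSE,
    stringsAsFactors = FALSE
  )
  cds <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    tr <- names(mrna_gene)[mrna_gene == gid]
    part <- cd[as.character(cd$Parent) %in% c(tr, gid), , drop = FALSE]
    if (nrow(part) == 0) next
    m <- cbind(start = part$start - 1L, end = part$end)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (sum(m[, 2] - m[, 1]) %% 3L != 0L) {
      warning("CDS length of ", gid, " not divisible by 3; flagged non-coding")
      next
    }
    cds[[gid]] <- m
    genes$coding[i] <- TRUE
  }
  annotated_genome(sequences, genes, cds)
}

#' Write a genome to FASTA and GFF3
#'
#' @param genome an [annotated_genome()].
#' @param fasta_path,gff3_path output paths.
#' @param width FASTA line width.
#' @export
write_genome <- function(genome, fasta_path, gff3_path, width = 60) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, fasta_path, width = width)
  con <- file(gff3_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  gn <- genome$genes[!genome$genes$deleted, , drop = FALSE]
  gn <- gn[order(gn$chrom_id, gn$start), , drop = FALSE]
  for (i in seq_len(nrow(gn))) {
    gid <- gn$gene_id[i]
    writeLines(sprintf(
      "%s\tdivaria\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      gn$chrom_id[i], gn$start[i] + 1L, gn$end[i], gn$strand[i], gid
    ), con)
    if (!gn$coding[i]) next
    writeLines(sprintf(
      "%s\tdivaria\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
      gn$chrom_id[i], gn$start[i] + 1L, gn$end[i], gn$strand[i], gid, gid
    ), con)
    m <- genome$cds[[gid]]
    for (j in seq_len(nrow(m))) {
      writeLines(sprintf(
        "%s\tdivaria\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds%d;Parent=%s.1",
        gn$chrom_id[i], m[j, 1] + 1L, m[j, 2], gn$strand[i], gid, j, gid
      ), con)
    }
  }
  invisible(NULL)
}

## 0-based half-open substring of a chromosome.
seq_slice <- function(sequences, chrom, start, end) {
  substr(sequences[[chrom]], start + 1L, end)
}

#' Extract the CDS of a gene
#'
#' CDS parts are concatenated in genomic order and reverse-complemented
#' for minus-strand genes, yielding the transcript-orientation CDS.
#'
#' @param genome an [annotated_genome()].
#' @param gene_id gene identifier.
#' @return DNA character scalar.
#' @export
extract_cds <- function(genome, gene_id) {
  i <- match(gene_id, genome$genes$gene_id)
  if (is.na(i)) stop("unknown gene: ", gene_id)
  if (isTRUE(genome$genes$deleted[i])) stop("gene deleted in this genome: ", gene_id)
  if (!genome$genes$coding[i]) stop("gene is non-coding: ", gene_id)
  m <- genome$cds[[gene_id]]
  ch <- genome$genes$chrom_id[i]
  parts <- vapply(seq_len(nrow(m)), function(j) {
    seq_slice(genome$sequences, ch, m[j, 1], m[j, 2])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (genome$genes$strand[i] == "-") s <- revcomp(s)
  s
}

#' Translate a CDS with the standard nuclear genetic code
#'
#' Stops render as `*`; codons containing N render as `X`; a trailing
#' partial codon is dropped with a warning.
#'
#' @param cds DNA character scalar.
#' @return protein character scalar.
#' @export
translate_dna <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    warning("CDS length not divisible by 3; truncating trailing bases")
    cds <- substr(cds, 1L, n - n %% 3L)
  }
  if (nchar(cds) == 0L) return("")
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Read / write a variant table
#'
#' Plain-TSV exchange format with columns CHROM, POS (1-based), TYPE
#' (SNP/INS/DEL/SV), REF, ALT, SVCLASS (deletion/duplication/other or
#' empty). Variants are expressed on the forward strand of the reference;
#' internally POS becomes a 0-based offset.
#'
#' @param path file path.
#' @return data.frame with columns chrom_id, pos (0-based), vtype,
#'   ref, alt, sv_class.
#' @export
read_variants <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  out <- data.frame(
    chrom_id = d$CHROM,
    pos = as.integer(d$POS) - 1L,
    vtype = d$TYPE,
    ref = d$REF,
    alt = ifelse(is.na(d$ALT), "", d$ALT),
    sv_class = if ("SVCLASS" %in% names(d)) ifelse(is.na(d$SVCLASS), "", d$SVCLASS) else "",
    stringsAsFactors = FALSE
  )
  validate_variants(out)
  out
}

#' @rdname read_variants
#' @param variants variant data.frame as returned by [read_variants()].
#' @export
write_variants <- function(variants, path) {
  d <- data.frame(
    CHROM = variants$chrom_id,
    POS = variants$pos + 1L,
    TYPE = variants$vtype,
    REF = variants$ref,
    ALT = variants$alt,
    SVCLASS = variants$sv_class
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_variants <- function(v) {
  stopifnot(all(v$vtype %in% c("SNP", "INS", "DEL", "SV")))
  snp <- v$vtype == "SNP"
  if (any(nchar(v$ref[snp]) != 1L | nchar(v$alt[snp]) != 1L)) {
    stop("SNP must have single-base ref and alt")
  }
  invisible(v)
}

#' Read a motif table
#'
#' TSV with columns motif_id and pattern (IUPAC degenerate DNA).
#'
#' @param path file path.
#' @return data.frame(motif_id, pattern).
#' @export
read_motifs <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("motif_id", "pattern") %in% names(d)))
  ok <- grepl("^[ACGTUWSMKRYBDHVN]+$", d$pattern)
  if (!all(ok)) {
    stop("invalid IUPAC pattern for motif: ",
         paste(d$motif_id[!ok], collapse = ", "))
  }
  d[, c("motif_id", "pattern")]
}
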