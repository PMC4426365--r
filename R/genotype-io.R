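# reading and writing homozygous multi-substrain variant calls
#
# The VCF dialect is minimal on purpose: VCFv4.2 header, CHROM/POS/REF/ALT,
# GT-only FORMAT with one sample column per substrain, all calls expected
# homozygous; the optional INFO key CSQ carries a consequence label.
# Multi-allelic records are split into biallelic records on load; rows with
# any heterozygous or missing genotype are dropped and counted.

#' Consequence labels treated as coding
#'
#' @return Character vector of VEP-style consequence labels counted as
#'   coding when classifying variants.
#' @export
defaultCodingSet <- function() {
  c(CODING_CONSEQUENCES, CODING_INDEL_CONSEQUENCES)
}

#' Load homozygous variant calls from a minimal VCF
#'
#' Parses a VCF with one sample column per substrain and GT-only
#' genotypes. Rows containing any heterozygous or missing call are
#' dropped and counted; multi-allelic records are split into biallelic
#' records (a sample homozygous for a different alternate allele renders
#' the split record missing for that sample, so the row is dropped).
#' The load report is attached as attribute `loadReport` and available
#' through [loadReport()].
#'
#' @param path path to the VCF file.
#' @param substrains optional character vector naming (and ordering) the
#'   sample columns to load; every name must be present in the file.
#' @param codingSet consequence labels classified as coding,
#'   see [defaultCodingSet()].
#' @return A [GenotypeTable-class]; `loadReport(x)` gives
#'   `list(kept =, dropped =)`.
#' @export
readGenotypeVcf <- function(path, substrains = NULL,
                            codingSet = defaultCodingSet()) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    sdStop("not a VCF: missing #CHROM header line", "parseError")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 10L || cols[9L] != "FORMAT")
    sdStop("VCF must have FORMAT and at least one sample column", "parseError")
  samples <- cols[-(1:9)]
  if (is.null(substrains)) substrains <- samples
  missing <- setdiff(substrains, samples)
  if (length(missing))
    sdStop(paste("unknown substrain column(s):",
                 paste(missing, collapse = ", ")), "inputError")
  sidx <- match(substrains, samples)

  recLines <- which(!startsWith(lines, "#") & nzchar(lines))
  recLines <- recLines[recLines > hdr]
  kept <- 0L; dropped <- 0L
  out <- vector("list", length(recLines))
  calls <- vector("list", length(recLines))
  n <- 0L
  for (ln in recLines) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(cols))
      sdStop(sprintf("malformed VCF line %d: expected %d fields, found %d",
                     ln, length(cols), length(f)), "parseError")
    pos <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(pos))
      sdStop(sprintf("malformed VCF line %d: POS is not a number", ln),
             "parseError")
    gtField <- strsplit(f[9L], ":", fixed = TRUE)[[1L]][1L]
    if (gtField != "GT")
      sdStop(sprintf("malformed VCF line %d: FORMAT must begin with GT", ln),
             "parseError")
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", 1L)[sidx]
    al <- strsplit(gts, "[/|]")
    bad <- vapply(al, function(a)
      length(a) != 2L || anyNA(suppressWarnings(as.integer(a))), TRUE)
    het <- !bad & vapply(al, function(a) a[1L] != a[2L], TRUE)
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    info <- f[8L]
    csq <- NA_character_
    if (grepl("(^|;)CSQ=", info))
      csq <- sub(";.*", "", sub(".*?(^|;)CSQ=", "", info))
    g <- suppressWarnings(vapply(al, function(a) as.integer(a[1L]), 1L))
    keptAny <- FALSE
    for (k in seq_along(alts)) {
      # a sample homozygous for a different alternate is missing for this
      # biallelic split record
      if (any(bad | het) || !all(g %in% c(0L, k))) next
      keptAny <- TRUE
      kept <- kept + 1L
      n <- n + 1L
      ref <- toupper(f[4L]); alt <- toupper(alts[k])
      cls <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNP" else "indel"
      out[[n]] <- data.frame(chrom = f[1L], pos = pos, ref = ref, alt = alt,
                             class = cls, consequence = csq,
                             coding = !is.na(csq) && csq %in% codingSet)
      calls[[n]] <- as.integer(g == k)
    }
    if (!keptAny) dropped <- dropped + 1L
  }
  if (n == 0L) {
    variants <- data.frame(chrom = character(0), pos = numeric(0),
                           ref = character(0), alt = character(0),
                           class = character(0), consequence = character(0),
                           coding = logical(0))
    cm <- matrix(integer(0), 0, length(substrains),
                 dimnames = list(NULL, substrains))
  } else {
    variants <- do.call(rbind, out[seq_len(n)])
    rownames(variants) <- NULL
    cm <- do.call(rbind, calls[seq_len(n)])
    colnames(cm) <- substrains
  }
  tbl <- new("GenotypeTable", variants = variants, calls = cm)
  attr(tbl, "loadReport") <- list(kept = kept, dropped = dropped)
  tbl
}

#' Load report of a genotype table read from disk
#'
#' @param x a [GenotypeTable-class] returned by [readGenotypeVcf()].
#' @return `list(kept =, dropped =)` record counts, or NULL if the table
#'   was not read from a file.
#' @export
loadReport <- function(x) attr(x, "loadReport")

#' Write a GenotypeTable as minimal VCF
#'
#' All calls are homozygous (`0/0` or `1/1`); the consequence label, when
#' present, is stored in the INFO key `CSQ`.
#'
#' @param table a [GenotypeTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(table, path) {
  stopifnot(is(table, "GenotypeTable"))
  v <- variantInfo(table); cm <- callsMatrix(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=SubstrainDrift",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(cm)), collapse = "\t")), con)
  if (nrow(v)) {
    info <- ifelse(is.na(v$consequence), ".", paste0("CSQ=", v$consequence))
    gt <- matrix(c("0/0", "1/1")[cm + 1L], nrow(cm), ncol(cm))
    body <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                  ".", v$ref, v$alt, ".", ".", info, "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read or write a GenotypeTable as TSV
#'
#' Columns: chrom, pos, ref, alt, class, consequence, coding, then one
#' 0/1 column per substrain.
#'
#' @param table a [GenotypeTable-class].
#' @param path file path.
#' @return `readGenotypeTsv` returns a [GenotypeTable-class];
#'   `writeGenotypeTsv` returns `path` invisibly.
#' @export
writeGenotypeTsv <- function(table, path) {
  stopifnot(is(table, "GenotypeTable"))
  df <- cbind(variantInfo(table), as.data.frame(callsMatrix(table)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeTsv
#' @export
readGenotypeTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta <- c("chrom", "pos", "ref", "alt", "class", "consequence", "coding")
  if (!all(meta %in% names(df)))
    sdStop("genotype TSV is missing metadata columns", "parseError")
  strains <- setdiff(names(df), meta)
  cm <- as.matrix(df[, strains, drop = FALSE])
  storage.mode(cm) <- "integer"
  v <- df[, meta, drop = FALSE]
  v$consequence <- as.character(v$consequence)
  v$pos <- as.numeric(v$pos)
  new("GenotypeTable", variants = v, calls = cm)
}
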