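# Plain-text readers/writers for the package's tabular formats.
# All tables are tab-separated with a header line; lines starting with '#'
# are metadata comments (the writers record the simulation seed there).

write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, colClasses = colClasses,
             na.strings = c("NA", ""))
}

#' Read or write a pool layout
#'
#' The TSV layout has columns `sample_id, individual_id, pool_id, role`
#' and optionally `pool_fraction`; a YAML layout (`.yml`/`.yaml`) is a list
#' of per-sample mappings with the same keys. Missing fractions default to
#' equal shares within each pool; fractions are normalised on load.
#'
#' @param path File to read from / write to.
#' @return [read_pool_layout()] returns a [pool_layout()];
#'   `write_pool_layout()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' write_pool_layout(pool_layout(c("T1", "T2"), c("A", "B"), "p1"), p)
#' read_pool_layout(p)
#' @export
read_pool_layout <- function(path) {
  if (!file.exists(path)) stop("layout file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    if (!is.null(entries$samples)) entries <- entries$samples
    get <- function(k, default = NA_character_)
      vapply(entries, function(e) {
        v <- e[[k]]
        if (is.null(v)) default else as.character(v)
      }, character(1))
    fr <- suppressWarnings(as.numeric(get("pool_fraction")))
    df <- data.frame(sample_id = get("sample_id"),
                     individual_id = get("individual_id"),
                     pool_id = get("pool_id"), role = get("role", "tumour"),
                     pool_fraction = fr, stringsAsFactors = FALSE)
  } else {
    df <- read_tsv(path, colClasses = "character")
    df$pool_fraction <- if ("pool_fraction" %in% names(df))
      suppressWarnings(as.numeric(df$pool_fraction)) else NA_real_
  }
  pool_layout(df$sample_id, df$individual_id, df$pool_id, df$role,
              df$pool_fraction)
}

#' @rdname read_pool_layout
#' @param layout A [pool_layout()].
#' @export
write_pool_layout <- function(layout, path) {
  stopifnot(inherits(layout, "pool_layout"))
  write_tsv(as.data.frame(layout), path)
}

#' Read or write a population allele-frequency table
#'
#' Accepts either a TSV with columns `chrom, pos, ref, alt, frequency` or a
#' sites-only VCF carrying the frequency in an INFO field (default `AF`).
#'
#' @param path File to read from / write to.
#' @param info_field INFO key holding the allele frequency when `path` is a
#'   VCF (default `"AF"`).
#' @return [read_frequency_table()] returns a [freq_table()].
#' @export
read_frequency_table <- function(path, info_field = "AF") {
  if (!file.exists(path)) stop("frequency file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    fr <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, info_field)))
    snv <- nchar(fx$REF) == 1 & nchar(fx$ALT) == 1 &
      fx$REF %in% BASES & fx$ALT %in% BASES
    if (anyNA(fr[snv]))
      stop("frequency VCF: missing/invalid ", info_field, " INFO field at record ",
           which(snv & is.na(fr))[1])
    return(freq_table(fx$CHROM[snv], as.integer(fx$POS[snv]),
                      fx$REF[snv], fx$ALT[snv], fr[snv]))
  }
  df <- read_tsv(path)
  need <- c("chrom", "pos", "ref", "alt", "frequency")
  if (!all(need %in% names(df)))
    stop("frequency table must have columns ", paste(need, collapse = ", "))
  bad <- which(is.na(df$frequency) | df$frequency < 0 | df$frequency > 1)
  if (length(bad))
    stop("frequency outside [0,1] at line ", bad[1] + 1L, " of ", path)
  freq_table(df$chrom, df$pos, df$ref, df$alt, df$frequency)
}

#' @rdname read_frequency_table
#' @param freqs A [freq_table()].
#' @export
write_frequency_table <- function(freqs, path) {
  stopifnot(inherits(freqs, "freq_table"))
  write_tsv(as.data.frame(freqs), path)
}

#' Read or write a pileup table
#'
#' TSV with columns `chrom, pos, ref, sample_id, nA, nC, nG, nT` and, for
#' simulator output, `origin_sample` identifying each read block's true
#' source library.
#'
#' @param path File to read from / write to.
#' @return [read_pileup()] returns a [pileup_counts()] data.frame.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  df <- read_tsv(path)
  for (cc in COUNT_COLS) df[[cc]] <- as.integer(df[[cc]])
  pileup_counts(df)
}

#' @rdname read_pileup
#' @param pileup A [pileup_counts()] table.
#' @param seed Optional integer recorded as a `# seed=` header comment.
#' @export
write_pileup <- function(pileup, path, seed = NULL) {
  stopifnot(inherits(pileup, "pileup_counts"))
  write_tsv(as.data.frame(pileup), path, seed = seed)
}
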