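# File formats: tab-separated tables with validated headers, PLINK1
# bed/bim/fam genotypes, YAML configs. All readers fail loudly with the
# offending column or line named.

sumstats_columns <- c("SNP", "CHR", "BP", "A1", "A2", "FREQ", "BETA", "SE",
                      "Z", "P", "N", "BETA_STD", "SE_STD")

#' Write / read summary statistics as TSV
#'
#' The on-disk schema is the column set produced by [run_scan()]:
#' `SNP CHR BP A1 A2 FREQ BETA SE Z P N BETA_STD SE_STD`. Reading validates
#' the header and refuses files with missing columns, naming them.
#'
#' @param ss Summary-statistics data frame.
#' @param path File path.
#' @return `read_sumstats` returns the validated data frame.
#' @export
write_sumstats <- function(ss, path) {
  miss <- setdiff(sumstats_columns, names(ss))
  if (length(miss))
    stop_ipw("summary statistics missing column(s): %s", paste(miss, collapse = ", "))
  utils::write.table(ss[, sumstats_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(sumstats_columns, names(ss))
  if (length(miss))
    stop_ipw("summary statistics file '%s' missing column(s): %s",
             path, paste(miss, collapse = ", "))
  ss
}

#' Write / read a cohort table as TSV
#'
#' Columns: `id`, the 14 auxiliary variables, `participation`,
#' `design_weight` and (synthetic cohorts only) `true_P`.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  coh <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- setdiff(c("id", aux_variables()), names(coh))
  if (length(need))
    stop_ipw("cohort file '%s' missing column(s): %s", path,
             paste(need, collapse = ", "))
  spec <- aux_spec()
  for (i in which(spec$type == "categorical")) {
    v <- spec$variable[i]
    coh[[v]] <- factor(coh[[v]], levels = spec$levels[[i]])
  }
  coh
}

#' Write probability weights as TSV
#'
#' @param ids Individual identifiers of the selected sample.
#' @param pw A `probability_weights` object.
#' @param path File path.
#' @export
write_weights_tsv <- function(ids, pw, path) {
  utils::write.table(
    data.frame(id = ids, P = pw$P, w = pw$w, w_in = pw$w_in),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as a dosage TSV
#'
#' Plain-text alternative to PLINK1: first columns are the SNP metadata,
#' remaining columns one dosage per individual.
#'
#' @param g A `genotype_set`.
#' @param path File path.
#' @export
write_dosage_tsv <- function(g, path) {
  tab <- cbind(g$snp_meta, as.data.frame(t(g$dosages)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read genotypes in PLINK1 bed/bim/fam format
#'
#' SNP-major PLINK1 binary coding (magic bytes 0x6c 0x1b 0x01; per SNP,
#' packed 2-bit genotypes, 4 individuals per byte, least-significant bits
#' first: 00 = two copies of A1, 10 = one copy, 11 = zero copies,
#' 01 = missing). Dosages count the A1 allele, so a write/read round trip
#' preserves the dosage matrix exactly.
#'
#' @param g A `genotype_set`.
#' @param prefix Path prefix; `.bed`, `.bim` and `.fam` are appended.
#' @param ids Optional individual ids for the fam file.
#' @return `read_plink` returns a `genotype_set`.
#' @export
write_plink <- function(g, prefix, ids = NULL) {
  d <- g$dosages
  n <- nrow(d); m <- ncol(d)
  ids <- ids %||% rownames(d) %||% sprintf("ind%06d", seq_len(n))
  # bim: chr, snp, cM, bp, a1, a2
  utils::write.table(
    data.frame(g$snp_meta$chr, g$snp_meta$snp, 0, g$snp_meta$bp,
               g$snp_meta$a1, g$snp_meta$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(ids, ids, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(3L, n, m)
  code[d == 2L] <- 0L
  code[d == 1L] <- 2L
  code[is.na(d)] <- 1L
  nb <- ceiling(n / 4)
  pad <- nb * 4 - n
  if (pad) code <- rbind(code, matrix(0L, pad, m))
  shifted <- code[seq(1, nb * 4, 4), , drop = FALSE] +
    code[seq(2, nb * 4, 4), , drop = FALSE] * 4L +
    code[seq(3, nb * 4, 4), , drop = FALSE] * 16L +
    code[seq(4, nb * 4, 4), , drop = FALSE] * 64L
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(shifted), con)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), stringsAsFactors = FALSE,
                           col.names = c("chr", "snp", "cm", "bp", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  nb <- ceiling(n / 4)
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + nb * m)
  if (length(raw) < 3 || !identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop_ipw("'%s.bed' is not a SNP-major PLINK1 bed file", prefix)
  body <- as.integer(raw[-(1:3)])
  # decode all 4 two-bit fields of every byte, then trim padding
  dos_map <- c(2L, NA_integer_, 1L, 0L)  # code 0,1,2,3
  codes <- rbind(bitwAnd(body, 3L),
                 bitwAnd(body %/% 4L, 3L),
                 bitwAnd(body %/% 16L, 3L),
                 bitwAnd(body %/% 64L, 3L))
  d <- matrix(dos_map[codes + 1L], nb * 4, m)[seq_len(n), , drop = FALSE]
  colnames(d) <- bim$snp
  rownames(d) <- fam$V2
  freq <- colMeans(d, na.rm = TRUE) / 2
  structure(list(
    dosages = d,
    snp_meta = data.frame(snp = bim$snp, chr = bim$chr, bp = bim$bp,
                          a1 = bim$a1, a2 = bim$a2, freq = freq,
                          stringsAsFactors = FALSE)),
    class = "genotype_set")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] (or any nested list of scalars).
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_recursive(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$scenario <- do.call(scenario_config, restore_config(cfg$scenario))
  do.call(pipeline_config, cfg)
}

unclass_recursive <- function(x) {
  if (is.matrix(x)) {
    return(list(.matrix = TRUE, data = as.numeric(x), nrow = nrow(x),
                rownames = rownames(x), colnames = colnames(x)))
  }
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  if (!is.null(names(x)) && is.numeric(x)) return(as.list(x))
  x
}

restore_config <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$data), nrow = x$nrow,
                  dimnames = list(unlist(x$rownames), unlist(x$colnames)))
      return(m)
    }
    if (length(x) && all(vapply(x, function(e)
      is.numeric(e) && length(e) == 1, logical(1)))) {
      return(unlist(x))
    }
    return(lapply(x, restore_config))
  }
  x
}

# Polynomial rolling hash (mod 2^31 - 1) for provenance stamping of artifacts.
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass_recursive(config))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
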