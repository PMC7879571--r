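# SNP quality control: the filter cascade applied to the multi-chip panel,
# with an auditable report.

#' Build a QC report table
#'
#' Validates the bookkeeping contract: remaining counts decrease
#' monotonically and the final count equals the initial count minus the sum
#' of removals.
#'
#' @param steps Tibble with columns `filter`, `threshold`, `n_removed`,
#'   `n_remaining`.
#' @param n_initial SNP count before the first filter.
#' @return A `qc_report` tibble.
#' @export
qc_report <- function(steps, n_initial) {
  check_columns(steps, c("filter", "threshold", "n_removed", "n_remaining"),
                "QC steps")
  prev <- c(n_initial, steps$n_remaining[-nrow(steps)])
  if (any(steps$n_remaining != prev - steps$n_removed)) {
    abort("QC report does not conserve counts (remaining != previous - removed)")
  }
  if (any(diff(c(n_initial, steps$n_remaining)) > 0)) {
    abort("QC remaining counts must be non-increasing")
  }
  if (any(steps$n_remaining < 0)) {
    abort("QC remaining counts cannot be negative")
  }
  structure(as_tibble(steps), n_initial = n_initial,
            class = c("qc_report", class(as_tibble(steps))))
}

#' Replay a QC cascade from removal counts alone
#'
#' Reconstructs the remaining-count column from an initial SNP count and the
#' per-filter removals, through the same validation as [qc_report()]. Useful
#' for auditing a published cascade without the genotypes.
#'
#' @param n_initial Initial SNP count.
#' @param removed Named integer vector of removals, in filter order.
#' @param thresholds Optional character vector of threshold descriptions.
#' @return A `qc_report` tibble.
#' @export
#' @examples
#' qc_replay(606343, c(maf = 196864, hwe = 25596,
#'                     call_rate = 6614, chip_maf = 1582))
qc_replay <- function(n_initial, removed, thresholds = NULL) {
  steps <- tibble(
    filter = names(removed) %||% paste0("step", seq_along(removed)),
    threshold = thresholds %||% rep(NA_character_, length(removed)),
    n_removed = as.integer(removed),
    n_remaining = as.integer(n_initial - cumsum(removed))
  )
  qc_report(steps, n_initial)
}

#' SNP quality-control cascade
#'
#' Applies, in this canonical order: unknown chromosome location, sex
#' chromosomes, duplicated (chromosome, position), minor allele frequency,
#' Hardy-Weinberg disequilibrium (Pearson chi-square, 1 df), call rate, and
#' cross-chip MAF consistency (pairwise allele-count chi-square between
#' chips; a SNP fails if any chip pair disagrees at `chip_maf_p`).
#'
#' @param gt A [genotype_matrix()].
#' @param thresholds Named list overriding any of `maf` (0.05), `hwe_p`
#'   (1e-6), `call_rate` (0.90), `chip_maf_p` (1e-5).
#' @return List with elements `gt` (filtered genotypes) and `report`
#'   (a [qc_report()] including every step).
#' @export
qc_cascade <- function(gt, thresholds = list()) {
  stopifnot(inherits(gt, "geno_matrix"))
  th <- utils::modifyList(
    list(maf = 0.05, hwe_p = 1e-6, call_rate = 0.90, chip_maf_p = 1e-5),
    thresholds)
  geno <- gt$geno
  map <- gt$map
  chrlab <- toupper(trimws(as.character(map$chr)))
  steps <- list()
  keep <- rep(TRUE, ncol(geno))
  note <- function(name, threshold, drop) {
    drop <- drop & keep
    keep <<- keep & !drop
    steps[[length(steps) + 1]] <<- tibble(
      filter = name, threshold = threshold,
      n_removed = sum(drop), n_remaining = sum(keep))
    if (!any(keep)) warn(sprintf("no SNPs remain after filter '%s'", name))
  }
  note("unplaced", "chromosome unknown",
       is.na(chrlab) | chrlab %in% c("", "0", "UN", "UNKNOWN", "NA"))
  note("sex_chromosomes", "X or Y", chrlab %in% c("X", "Y"))
  note("duplicates", "same chromosome and position",
       duplicated(paste(chrlab, map$pos)))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  note("maf", sprintf("MAF < %g", th$maf), maf < th$maf)
  note("hwe", sprintf("HWE P < %g", th$hwe_p), hwe_pvalue(geno) < th$hwe_p)
  cr <- colMeans(!is.na(geno))
  note("call_rate", sprintf("call rate < %g", th$call_rate), cr < th$call_rate)
  note("chip_maf_consistency", sprintf("chip MAF P < %g", th$chip_maf_p),
       chip_maf_pvalue(geno, gt$chip) < th$chip_maf_p)
  report <- qc_report(bind_rows(steps), ncol(geno))
  out <- genotype_matrix(geno[, keep, drop = FALSE], map[keep, ], gt$chip)
  list(gt = out, report = report)
}

# Pearson chi-square (1 df) Hardy-Weinberg p-value per SNP column
hwe_pvalue <- function(geno) {
  n0 <- colSums(geno == 0, na.rm = TRUE)
  n1 <- colSums(geno == 1, na.rm = TRUE)
  n2 <- colSums(geno == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2
  e1 <- 2 * n * p * q
  e2 <- n * p^2
  stat <- (n0 - e0)^2 / pmax(e0, .Machine$double.eps) +
    (n1 - e1)^2 / pmax(e1, .Machine$double.eps) +
    (n2 - e2)^2 / pmax(e2, .Machine$double.eps)
  pval <- pchisq(stat, df = 1, lower.tail = FALSE)
  pval[p %in% c(0, 1)] <- 1   # monomorphic: HWE trivially holds
  pval
}

# smallest pairwise allele-count chi-square p-value across chips, per SNP
chip_maf_pvalue <- function(geno, chip) {
  chips <- unique(chip)
  if (length(chips) < 2) return(rep(1, ncol(geno)))
  counts <- lapply(chips, function(cp) {
    g <- geno[chip == cp, , drop = FALSE]
    alt <- colSums(g, na.rm = TRUE)
    tot <- 2 * colSums(!is.na(g))
    cbind(alt = alt, ref = tot - alt)
  })
  pmin_p <- rep(1, ncol(geno))
  for (a in seq_along(chips)[-length(chips)]) {
    for (b in seq.int(a + 1, length(chips))) {
      x1 <- counts[[a]][, "alt"]; y1 <- counts[[a]][, "ref"]
      x2 <- counts[[b]][, "alt"]; y2 <- counts[[b]][, "ref"]
      n <- x1 + y1 + x2 + y2
      ok <- (x1 + y1) > 0 & (x2 + y2) > 0 & (x1 + x2) > 0 & (y1 + y2) > 0
      stat <- rep(0, ncol(geno))
      stat[ok] <- (n * (x1 * y2 - x2 * y1)^2 /
                     ((x1 + y1) * (x2 + y2) * (x1 + x2) * (y1 + y2)))[ok]
      pmin_p <- pmin(pmin_p, pchisq(stat, df = 1, lower.tail = FALSE))
    }
  }
  pmin_p
}
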