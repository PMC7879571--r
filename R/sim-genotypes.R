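#' Genotype container
#'
#' Couples an animals-by-SNPs dosage matrix (0/1/2, `NA` missing) with its
#' SNP map and the chip of origin of each animal.
#'
#' @param geno Integer dosage matrix, rownames = animal ids.
#' @param map Tibble with columns `snp_id`, `chr`, `pos` (1-based) and
#'   optionally allele columns `a1`, `a2`.
#' @param chip Character vector (one entry per animal) naming the genotyping
#'   chip; defaults to a single chip.
#' @return A `geno_matrix` list.
#' @export
genotype_matrix <- function(geno, map, chip = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) abort("`geno` needs animal ids as rownames")
  check_columns(map, c("snp_id", "chr", "pos"), "SNP map")
  if (ncol(geno) != nrow(map)) {
    abort("`geno` columns and `map` rows must agree")
  }
  colnames(geno) <- map$snp_id
  chip <- chip %||% rep("chip1", nrow(geno))
  if (length(chip) != nrow(geno)) abort("`chip` must have one entry per animal")
  ok <- is.na(geno) | (geno %in% 0:2)
  if (!all(ok)) abort("dosages must be 0, 1, 2 or NA")
  structure(list(geno = geno, map = as_tibble(map), chip = chip),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d animals x %d SNPs; chips: %s\n",
              nrow(x$geno), ncol(x$geno),
              paste(unique(x$chip), collapse = ", ")))
  invisible(x)
}

#' Simulate SNP genotypes by gene dropping
#'
#' Founder allele frequencies are drawn from `cfg$maf_range`; founders are in
#' Hardy-Weinberg proportions in expectation and every non-founder inherits
#' one gamete from each parent by Mendelian segregation. An unknown parent
#' contributes a gamete drawn from the founder allele frequencies.
#'
#' @param ped A pedigree.
#' @param cfg A [sim_config()].
#' @param n_chips Number of chips to attribute animals to (provenance only;
#'   all chips carry all simulated SNPs unless QC masks are applied later).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(ped, cfg, n_chips = 1L) {
  ped <- as_pedigree(ped)
  with_stream(cfg$seed, "genotypes", {
    pi <- ped_index(ped)
    n <- nrow(ped)
    m <- cfg$n_snps
    p <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    geno <- matrix(0L, n, m, dimnames = list(pi$id, NULL))
    s <- pi$sire
    d <- pi$dam
    # process whole pedigree depth levels at once: one segregation draw per
    # (animal, SNP), parents always in an earlier level
    depth <- integer(n)
    for (i in seq_len(n)) {
      dp <- c(if (!is.na(s[i])) depth[s[i]], if (!is.na(d[i])) depth[d[i]], -1L)
      depth[i] <- max(dp) + 1L
    }
    gametes_from <- function(par, rows) {
      # one transmitted allele per (animal, SNP) for a block of animals
      k <- length(rows)
      out <- matrix(0L, k, m)
      known <- !is.na(par)
      if (any(known)) {
        pg <- geno[par[known], , drop = FALSE]
        out[known, ] <- (pg == 2L) +
          (pg == 1L) * matrix(rbinom(sum(known) * m, 1L, 0.5), ncol = m)
      }
      if (any(!known)) {
        out[!known, ] <- matrix(rbinom(sum(!known) * m, 1L,
                                       rep(p, each = sum(!known))), ncol = m)
      }
      out
    }
    for (lev in sort(unique(depth))) {
      rows <- which(depth == lev)
      geno[rows, ] <- gametes_from(s[rows], rows) + gametes_from(d[rows], rows)
    }
    chrs <- rep(1:31, length.out = m)
    map <- tibble(
      snp_id = sprintf("snp%05d", seq_len(m)),
      chr = as.character(chrs),
      pos = 1000L * (seq_len(m) %/% 31L + 1L) + chrs,
      a1 = "A", a2 = "B"
    )
    chip <- paste0("chip", rep_len(seq_len(n_chips), n))
    genotype_matrix(geno, map, chip)
  })
}
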