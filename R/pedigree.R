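#' Validate and topologically sort a pedigree
#'
#' A pedigree is a tibble with columns `id`, `sire`, `dam` (parent columns use
#' `NA` for unknown). Animals are reordered so that parents always precede
#' their offspring (stable topological sort, with `birth_year` as tie-break
#' when present), which the tabular relationship-matrix method requires.
#'
#' @param ped A data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex`, `birth_year`, `generation`. `0`, `""` and `NA` all denote an
#'   unknown parent.
#' @return A tibble of class `ped_df`, topologically sorted.
#' @export
#' @examples
#' as_pedigree(data.frame(id = c(3, 1, 2), sire = c(1, NA, NA),
#'                        dam = c(2, NA, NA)))
as_pedigree <- function(ped) {
  if (inherits(ped, "ped_df")) return(ped)   # already validated and sorted
  check_columns(ped, c("id", "sire", "dam"), "pedigree")
  ped <- as_tibble(ped)
  norm <- function(x) {
    x[!is.na(x) & (x == 0 | x == "")] <- NA
    x
  }
  ped$sire <- norm(ped$sire)
  ped$dam <- norm(ped$dam)
  if (anyDuplicated(ped$id)) abort("pedigree ids must be unique")
  if (any(!is.na(ped$sire) & ped$sire == ped$id) ||
      any(!is.na(ped$dam) & ped$dam == ped$id)) {
    abort("an animal cannot be its own parent")
  }
  # parents that never appear as animals become founder rows
  known_parents <- setdiff(unique(c(ped$sire, ped$dam)), c(ped$id, NA))
  if (length(known_parents)) {
    add <- tibble(id = known_parents, sire = NA, dam = NA)
    for (col in setdiff(names(ped), names(add))) add[[col]] <- NA
    ped <- bind_rows(add[names(ped)], ped)
  }
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- as.character(ped$id)
  si <- unname(idx[as.character(ped$sire)])
  di <- unname(idx[as.character(ped$dam)])
  # generation depth by fixed-point iteration (vectorised topological sort);
  # a cycle never stabilises and is caught by the iteration cap
  depth <- integer(n)
  si1 <- ifelse(is.na(si), 1L, si)
  di1 <- ifelse(is.na(di), 1L, di)
  for (pass in seq_len(n + 1L)) {
    ds <- ifelse(is.na(si), -1L, depth[si1])
    dd <- ifelse(is.na(di), -1L, depth[di1])
    nd <- pmax(ds, dd) + 1L
    if (all(nd == depth)) break
    if (pass > n) abort("pedigree contains a cycle (an animal is its own ancestor)")
    depth <- nd
  }
  key <- if ("birth_year" %in% names(ped)) {
    by <- as.numeric(ped$birth_year)
    by[is.na(by)] <- -Inf
    by
  } else {
    rep(0, n)
  }
  ped <- ped[order(depth, key, seq_len(n)), ]
  class(ped) <- c("ped_df", class(ped))
  ped
}

# integer parent indices (NA = unknown) for a sorted pedigree
ped_index <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- as.character(ped$id)
  list(
    sire = unname(idx[as.character(ped$sire)]),
    dam = unname(idx[as.character(ped$dam)]),
    id = as.character(ped$id)
  )
}

#' Extract a focal set and its recent ancestors from a pedigree
#'
#' Keeps the focal animals plus all ancestors within `n_generations`
#' meioses; parents beyond the horizon are set to unknown.
#'
#' @param ped A pedigree (coerced with [as_pedigree()]).
#' @param focal Ids of the focal animals.
#' @param n_generations Number of ancestral generations to retain.
#' @return A `ped_df` tibble restricted to the extracted animals.
#' @export
extract_ancestors <- function(ped, focal, n_generations) {
  ped <- as_pedigree(ped)
  if (!all(as.character(focal) %in% as.character(ped$id))) {
    abort("some focal ids are absent from the pedigree")
  }
  depth <- setNames(rep(Inf, nrow(ped)), as.character(ped$id))
  depth[as.character(focal)] <- 0
  frontier <- as.character(focal)
  g <- 0
  pmap_ <- setNames(seq_len(nrow(ped)), as.character(ped$id))
  while (length(frontier) && g < n_generations) {
    rows <- pmap_[frontier]
    nxt <- unique(stats::na.omit(c(as.character(ped$sire[rows]),
                                   as.character(ped$dam[rows]))))
    nxt <- nxt[depth[nxt] > g + 1]
    depth[nxt] <- g + 1
    frontier <- nxt
    g <- g + 1
  }
  kept <- names(depth)[is.finite(depth)]
  out <- ped[as.character(ped$id) %in% kept, ]
  out$sire[!(as.character(out$sire) %in% kept)] <- NA
  out$dam[!(as.character(out$dam) %in% kept)] <- NA
  as_pedigree(out)
}

#' Read / write a pedigree CSV
#'
#' Columns `id`, `sire`, `dam` (0 or empty marks an unknown parent), plus any
#' extra columns such as `sex` and `birth_year`.
#'
#' @param path File path.
#' @return `read_pedigree()` returns a sorted `ped_df` tibble.
#' @export
read_pedigree <- function(path) {
  as_pedigree(readr::read_csv(path, show_col_types = FALSE))
}

#' @param ped Pedigree to write.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  out <- as_tibble(ped)
  out$sire[is.na(out$sire)] <- 0
  out$dam[is.na(out$dam)] <- 0
  readr::write_csv(out, path)
  invisible(path)
}

#' Maternal-grandsire view of a pedigree
#'
#' @param ped A pedigree.
#' @return Tibble with columns `id`, `sire`, `mgs` (dam's sire, `NA` when the
#'   dam or her sire is unknown).
#' @export
ped_mgs_view <- function(ped) {
  ped <- as_pedigree(ped)
  dam_sire <- setNames(ped$sire, as.character(ped$id))
  tibble(
    id = ped$id,
    sire = ped$sire,
    mgs = unname(dam_sire[as.character(ped$dam)])
  )
}
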