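# Small fixtures shared across test files; everything is built in code.

# 3-generation pedigree of moderate size, deterministic
small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_founders = 20, n_generations = 2,
             progeny_per_sire = 3, n_snps = 200, ...)
}

small_ped <- function(cfg = small_cfg()) simulate_pedigree(cfg)

# half-sib design: `ns` founder sires, `nfam` of them with `npro` progeny
# each (dams unknown) - the layout of the sire-model experiments
halfsib_ped <- function(ns, nfam, npro) {
  as_pedigree(tibble::tibble(
    id = seq_len(ns + nfam * npro),
    sire = c(rep(NA, ns), rep(seq_len(nfam), each = npro)),
    dam = NA,
    sex = c(rep("M", ns), rep("F", nfam * npro)),
    birth_year = c(rep(1990L, ns), rep(2011L, nfam * npro)),
    generation = c(rep(0L, ns), rep(1L, nfam * npro))
  ))
}

# textbook 5-animal pedigree: founders 1,2; full sibs 3,4; their offspring 5
fullsib_ped <- function() {
  data.frame(id = 1:5, sire = c(NA, NA, 1, 1, 3), dam = c(NA, NA, 2, 2, 4))
}
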