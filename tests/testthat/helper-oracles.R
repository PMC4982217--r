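# Independent oracles and small fixture builders shared across tests.

# Exact two-sided Wilcoxon rank-sum p-value by brute-force enumeration of
# all assignments of the combined ranks to group b (tie-free data only).
oracle_exact_wilcox_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(!anyDuplicated(c(a, b)))
  r <- rank(c(a, b))
  U_obs <- sum(r[(na + 1):(na + nb)]) - nb * (nb + 1) / 2
  combs <- utils::combn(na + nb, nb)
  Us <- apply(combs, 2, function(idx) sum(r[idx]) - nb * (nb + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# quick assay_matrix from a plain matrix, labelling rows/cols if needed
make_am <- function(m, scale_tag = "raw", bead_counts = NULL) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    rownames(m) <- sprintf("A%02d", seq_len(nrow(m)))
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  assay_matrix(m, bead_counts = bead_counts, scale_tag = scale_tag)
}

# a small but realistic simulated dataset reused by slower tests
small_sim <- function(seed = 42, ...) {
  simulate_assay(sim_config(n_analytes = 60, seed = seed, ...))
}
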