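# shared builders for small test fixtures (all generated in code)

tiny_item_map <- function(n_items = 8, n_traits = 2) {
  trait <- rep(seq_len(n_traits), length.out = n_items)
  names(trait) <- paste0("i", seq_len(n_items))
  sort_by_trait <- order(trait)
  trait[sort_by_trait]
}

# fast MH-RM schedule for unit tests
light_control <- function(...) {
  mnrm_control(burnin = 40L, stage2_max = 120L, mh_sweeps = 2L,
               mh_sweeps_burnin = 3L, ...)
}

# desk-scale schedule used by the acceptance study runs
study_control <- function(...) {
  mnrm_control(burnin = 50L, stage2_max = 150L, mh_sweeps = 2L,
               mh_sweeps_burnin = 3L, ...)
}

random_faking_weights <- function(n_items, K1) {
  m <- matrix(runif(n_items * K1), n_items, K1)
  m[, 1] <- 0; m[, K1] <- 1
  m
}
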