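# Small in-code fixtures shared across the suite.

# Random log-normal measurement table with no group structure.
rand_table <- function(n = 8, p = 4, seed = 1, sigma = 0.1) {
  set.seed(seed)
  vals <- exp(matrix(rnorm(n * p, log(500), sigma), n, p))
  colnames(vals) <- paste0("ch", seq_len(p))
  measurement_table(vals, group = rep("g", n), sex = rep("female", n))
}

# Two groups separated purely in shape along (e_j - e_k); equal sizes.
shape_pair_table <- function(n = 20, p = 6, delta = 0.3, sigma = 0.03,
                             seed = 1) {
  chars <- paste0("ch", seq_len(p))
  off <- rep(0, p); off[1] <- delta / 2; off[2] <- -delta / 2
  spec <- morpho_gen_spec(list(
    list(label = "A", sex = "female", n = n, size_mean = log(500),
         size_sd = 0.05, shape_offset = off, resid_sd = sigma),
    list(label = "B", sex = "female", n = n, size_mean = log(500),
         size_sd = 0.05, shape_offset = -off, resid_sd = sigma)),
    characters = chars, seed = seed)
  gen_morpho(spec)
}

# Tiny aligned set from literal strings.
aln_from_strings <- function(...) {
  s <- c(...)
  aligned_seq_set(s, id = names(s))
}

# Independent two-sample standard distance of a 1-D variable
# (classical pooled-SD formula, no matrix algebra).
oracle_sd_1d <- function(x1, x2) {
  sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x2) - 1) * var(x2)) /
               (length(x1) + length(x2) - 2))
  abs(mean(x1) - mean(x2)) / sp
}
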