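# Brute-force oracle for the probability that n i.i.d. categorical draws
# from p cover every category: enumerate all k^n ordered sequences.
# Independent of the inclusion-exclusion implementation; only feasible for
# tiny k and n.
enumerate_full_prob <- function(p, n) {
  k <- length(p)
  if (n == 0) return(if (k == 0) 1 else 0)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  total <- 0
  for (r in seq_len(nrow(seqs))) {
    s <- seqs[r, ]
    if (length(unique(s)) == k) total <- total + prod(p[s])
  }
  total
}

# small long-format count table for two individuals over two groups
tiny_long_df <- function() {
  data.frame(
    individual_id = c("w1", "w1", "n1", "n1"),
    colony_id = c("I", "I", "II", "II"),
    caste_group = c("worker", "worker", "nymph", "nymph"),
    sex = c("unknown", "unknown", "female", "female"),
    species_group = rep(c("Trichonympha_agilis", "Teranympha_mirabilis"), 2),
    count = c(400L, 100L, 30L, 10L),
    stringsAsFactors = FALSE
  )
}

write_tmp_table <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  sep <- if (ext == "csv") "," else "\t"
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# minimal wide sample table built directly in code
tiny_wide_samples <- function(totals, caste = "A7", prefix = "a") {
  panel <- default_species_groups()$name
  n <- length(totals)
  counts <- matrix(0L, n, length(panel), dimnames = list(NULL, panel))
  counts[, 1] <- as.integer(totals)
  out <- data.frame(
    individual_id = paste0(prefix, seq_len(n)),
    colony_id = "I", caste_group = caste, sex = "unknown",
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(counts))
  out$total <- as.integer(totals)
  out
}

# random compositions bounded away from zero (all groups genuinely present,
# like the empirical panel where the rarest group still makes up ~0.1%)
random_composition <- function(k, floor_mass = 0.1) {
  raw <- rgamma(k, 1)
  p <- raw / sum(raw)
  (1 - floor_mass) * p + floor_mass / k
}
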