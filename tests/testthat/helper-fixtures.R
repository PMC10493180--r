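# Shared fixtures, built in code.

# Tiny deterministic bundle: 6 drugs in 2 latent groups, 2 modalities,
# labels follow the group pair (3 events: 1-1, 1-2, 2-2).
tiny_bundle <- function() {
  ids <- paste0("D", 1:6)
  grp <- c(1, 1, 1, 2, 2, 2)
  f1 <- matrix(0L, 6, 8)
  f1[grp == 1, 1:4] <- 1L
  f1[grp == 2, 5:8] <- 1L
  f1[1, 5] <- 1L                               # a little cross-group overlap
  f2 <- matrix(rep(c(1L, 0L), length.out = 48), 6, 8)  # fixed non-group pattern
  fm1 <- feature_matrix(f1, ids, paste0("a", 1:8), "alpha")
  fm2 <- feature_matrix(f2, ids, paste0("b", 1:8), "beta")
  pairs_ij <- rbind(c(1, 2), c(1, 3), c(2, 3),           # within group 1
                    c(1, 4), c(2, 5), c(3, 6), c(1, 5),  # cross
                    c(4, 5), c(4, 6), c(5, 6))           # within group 2
  ev <- c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3)
  pd <- pair_dataset(ids, pairs_ij[, 1], pairs_ij[, 2], ev,
                     c("within_A", "cross", "within_B"))
  dataset_bundle(list(fm1, fm2), pd)
}

# Brute-force set-based Jaccard oracle (independent of the matrix path).
oracle_jaccard_matrix <- function(M) {
  m <- nrow(M)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    Xi <- which(M[i, ] == 1); Xj <- which(M[j, ] == 1)
    inter <- length(intersect(Xi, Xj))
    uni <- length(union(Xi, Xj))
    S[i, j] <- if (uni == 0) 0 else inter / uni
  }
  S
}

# Reduced-width network used where full-size training would waste test time;
# architecture family, dropout, epochs, batch size and loss are unchanged.
desk_config <- function(seed = 1L, epochs = 100L)
  model_config(hidden_sizes = c(128L, 64L), epochs = epochs, seed = seed)

# Quick learnable synthetic world shared by several tests.
small_world <- function(seed = 3L, n_pairs = 500L, label_noise = 0)
  generate_bundle(synth_config(m = 60, p = 2, feature_counts = c(120, 90),
                               n_events = 5, n_pairs = n_pairs, n_groups = 3,
                               label_noise = label_noise, seed = seed))
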