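# Synthetic benchmark generator. Emulates the statistical structure the
# pipeline assumes: drugs fall into latent groups; within a "signal"
# modality each group has a characteristic subset of binary features, so
# within-group Jaccard similarity exceeds between-group similarity; the
# event label of a drug pair is a function of the two drugs' groups. This
# gives an end-to-end parameter-recovery oracle (zero label noise => a
# learnable problem) plus planted-signal structure for ablation oracles.

#' Synthetic bundle configuration
#'
#' @param m number of drugs.
#' @param p number of modalities.
#' @param feature_counts integer vector (length p) of per-modality column
#'   counts.
#' @param n_events number of event labels; must not exceed
#'   `n_groups*(n_groups+1)/2` (each unordered group pair maps to at most
#'   one event).
#' @param n_pairs total number of labeled drug pairs to sample.
#' @param n_groups latent group count (default: smallest count whose
#'   unordered group pairs can host `n_events` events).
#' @param within_group_on_prob probability a drug carries a feature from its
#'   group's profile (strong-profile default 0.9).
#' @param between_noise_prob probability a drug carries an off-profile
#'   feature in a signal modality (default 0.02).
#' @param noise_on_prob feature rate in non-signal (pure noise) modalities
#'   (default 0.1: sparse but dense enough to yield nonzero similarities).
#' @param profile_frac fraction of a signal modality's columns in each
#'   group's profile (default 0.15, at least 3 columns).
#' @param label_noise probability a pair's label is flipped to a uniformly
#'   random other event (default 0).
#' @param event_imbalance power-law exponent for event frequencies (weight
#'   of the r-th event proportional to r^-exponent; 0 = balanced, default 1
#'   mimics the heavy skew of real event distributions).
#' @param signal_modalities indices (into 1..p) of modalities carrying group
#'   structure; default all.
#' @param modality_names labels; default mod1..modp.
#' @param seed integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(m, p, feature_counts, n_events, n_pairs,
                         n_groups = min_groups_for(n_events),
                         within_group_on_prob = 0.9,
                         between_noise_prob = 0.02,
                         noise_on_prob = 0.1,
                         profile_frac = 0.15,
                         label_noise = 0,
                         event_imbalance = 1,
                         signal_modalities = seq_len(p),
                         modality_names = paste0("mod", seq_len(p)),
                         seed = 1L) {
  if (length(feature_counts) != p) stop("synth_config: feature_counts must have length p")
  if (n_events > n_groups * (n_groups + 1) / 2)
    stop("synth_config: n_events exceeds n_groups*(n_groups+1)/2 unordered group pairs")
  if (n_pairs > m * (m - 1) / 2)
    stop("synth_config: n_pairs exceeds m*(m-1)/2 distinct pairs")
  probs <- c(within_group_on_prob, between_noise_prob, noise_on_prob, label_noise)
  if (any(probs < 0 | probs > 1) || label_noise >= 1)
    stop("synth_config: probabilities must be in [0, 1] (label_noise < 1)")
  if (!all(signal_modalities %in% seq_len(p)))
    stop("synth_config: signal_modalities out of range")
  structure(list(m = as.integer(m), p = as.integer(p),
                 feature_counts = as.integer(feature_counts),
                 n_events = as.integer(n_events), n_pairs = as.integer(n_pairs),
                 n_groups = as.integer(n_groups),
                 within_group_on_prob = within_group_on_prob,
                 between_noise_prob = between_noise_prob,
                 noise_on_prob = noise_on_prob, profile_frac = profile_frac,
                 label_noise = label_noise, event_imbalance = event_imbalance,
                 signal_modalities = as.integer(signal_modalities),
                 modality_names = modality_names, seed = as.integer(seed)),
            class = "synth_config")
}

# Smallest g with g*(g+1)/2 >= n (unordered group pairs, same-group allowed).
min_groups_for <- function(n_events) {
  g <- ceiling((sqrt(8 * n_events + 1) - 1) / 2)
  as.integer(g)
}

#' Generate a synthetic dataset bundle with known ground truth
#'
#' Drugs are dealt (shuffled round-robin) into `n_groups` balanced latent
#' groups. A seeded random injection maps each event to a distinct unordered
#' group pair. Event frequencies follow a power law in `event_imbalance`;
#' each event's pairs are sampled without replacement from the drug pairs of
#' its group pair, so each unordered drug pair occurs at most once and
#' carries exactly one label. Labels are then flipped with probability
#' `label_noise`. Signal modalities get group feature profiles
#' (on-probability `within_group_on_prob` inside the profile,
#' `between_noise_prob` outside); non-signal modalities are i.i.d. Bernoulli
#' noise at `noise_on_prob`.
#'
#' @param config a [synth_config].
#' @return List: `bundle` (a [dataset_bundle]) and `ground_truth` (list with
#'   `groups`, `event_map` data frame, `profiles`, `config`).
#' @export
generate_bundle <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    m <- cfg$m; ng <- cfg$n_groups
    drug_ids <- sprintf("drug_%03d", seq_len(m))
    groups <- sample(rep_len(seq_len(ng), m))          # balanced assignment

    gp <- which(upper.tri(diag(ng), diag = TRUE), arr.ind = TRUE)  # g1 <= g2
    ev_gp <- sample(nrow(gp), cfg$n_events)            # random injection
    event_map <- data.frame(event = seq_len(cfg$n_events),
                            g1 = gp[ev_gp, 1L], g2 = gp[ev_gp, 2L])

    # target counts: power-law weights over events, every event >= 1 record
    w <- seq_len(cfg$n_events)^(-cfg$event_imbalance)
    counts <- pmax(1L, round(cfg$n_pairs * w / sum(w)))

    members <- split(seq_len(m), groups)
    rec_i <- integer(0); rec_j <- integer(0); rec_e <- integer(0)
    for (e in seq_len(cfg$n_events)) {
      a <- members[[event_map$g1[e]]]; b <- members[[event_map$g2[e]]]
      if (event_map$g1[e] == event_map$g2[e]) {
        if (length(a) < 2L) stop("generate_bundle: group ", event_map$g1[e],
                                 " too small for within-group pairs")
        cand <- t(utils::combn(a, 2L))
      } else {
        cand <- as.matrix(expand.grid(i = a, j = b))
      }
      take <- cand[sample(nrow(cand), min(counts[e], nrow(cand))), , drop = FALSE]
      rec_i <- c(rec_i, pmin(take[, 1L], take[, 2L]))
      rec_j <- c(rec_j, pmax(take[, 1L], take[, 2L]))
      rec_e <- c(rec_e, rep(e, nrow(take)))
    }
    if (cfg$label_noise > 0 && cfg$n_events > 1L) {
      flip <- which(stats::runif(length(rec_e)) < cfg$label_noise)
      for (ix in flip) {
        others <- setdiff(seq_len(cfg$n_events), rec_e[ix])
        rec_e[ix] <- others[sample.int(length(others), 1L)]
      }
    }
    # shuffle record order so fold construction sees no event blocks
    o <- sample(length(rec_e))
    pairs <- pair_dataset(drug_ids, rec_i[o], rec_j[o], rec_e[o],
                          sprintf("event_%03d", seq_len(cfg$n_events)))

    profiles <- vector("list", cfg$p)
    feats <- vector("list", cfg$p)
    for (kmod in seq_len(cfg$p)) {
      cc <- cfg$feature_counts[kmod]
      cols <- sprintf("%s_f%04d", cfg$modality_names[kmod], seq_len(cc))
      if (kmod %in% cfg$signal_modalities) {
        psize <- max(3L, round(cfg$profile_frac * cc))
        prof <- lapply(seq_len(ng), function(g) sample(cc, min(psize, cc)))
        P <- matrix(cfg$between_noise_prob, m, cc)
        for (g in seq_len(ng))
          P[groups == g, prof[[g]]] <- cfg$within_group_on_prob
        profiles[[kmod]] <- prof
      } else {
        P <- matrix(cfg$noise_on_prob, m, cc)
      }
      V <- matrix(stats::rbinom(m * cc, 1L, as.vector(P)), m, cc)
      feats[[kmod]] <- feature_matrix(V, drug_ids, cols, cfg$modality_names[kmod])
    }
    list(bundle = dataset_bundle(feats, pairs),
         ground_truth = list(groups = groups, event_map = event_map,
                             profiles = profiles, config = cfg))
  })
}

# Printed benchmark shapes (drugs, per-modality feature counts, events,
# interaction counts) used to derive scaled synthetic configurations.
ds_shapes <- list(
  DS1 = list(m = 572L, interactions = 37264L, n_events = 65L,
             feature_counts = c(mono_side_effect = 9991L, target = 1162L,
                                enzyme = 202L, chemical_substructure = 881L,
                                pathway = 957L)),
  DS2 = list(m = 1258L, interactions = 161770L, n_events = 100L,
             feature_counts = c(target = 1651L, enzyme = 316L,
                                chemical_substructure = 2040L)),
  DS3 = list(m = 645L, interactions = 63473L, n_events = 185L,
             feature_counts = c(mono_side_effect = 10184L, target = 8934L)))

#' Benchmark-shaped synthetic configuration
#'
#' Returns a [synth_config] whose drug count, per-modality feature counts
#' and event count equal a benchmark's printed values multiplied by `scale`
#' (rounded, with minimums enforced: at least 20 drugs, 10 features per
#' modality, 2 events). The modality count p is a property of the benchmark
#' and is never scaled. The pair count scales with `scale^2`, preserving
#' the benchmark's pair density.
#'
#' @param dataset `"DS1"`, `"DS2"` or `"DS3"`.
#' @param scale factor in (0, 1].
#' @param ... overrides passed on to [synth_config()] (e.g. `label_noise`,
#'   `signal_modalities`, `seed`).
#' @return A [synth_config].
#' @export
make_ds_shaped <- function(dataset = c("DS1", "DS2", "DS3"), scale = 1.0, ...) {
  dataset <- match.arg(dataset)
  if (scale <= 0 || scale > 1) stop("make_ds_shaped: scale must be in (0, 1]")
  sh <- ds_shapes[[dataset]]
  m <- max(20L, as.integer(round(sh$m * scale)))
  n_events <- max(2L, as.integer(round(sh$n_events * scale)))
  n_pairs <- min(as.integer(round(sh$interactions * scale^2)),
                 as.integer(m * (m - 1) / 2))
  synth_config(m = m, p = length(sh$feature_counts),
               feature_counts = pmax(10L, as.integer(round(sh$feature_counts * scale))),
               n_events = n_events, n_pairs = n_pairs,
               modality_names = names(sh$feature_counts), ...)
}

#' Write ground truth next to a written bundle
#'
#' Sidecar TSVs: `groups.tsv` (drug, latent group) and `event_map.tsv`
#' (event, group pair).
#'
#' @param ground_truth the `ground_truth` element of [generate_bundle()].
#' @param dir directory (typically the [write_bundle()] directory).
#' @export
write_ground_truth <- function(ground_truth, dir) {
  ids <- sprintf("drug_%03d", seq_along(ground_truth$groups))
  utils::write.table(data.frame(drug_id = ids, group = ground_truth$groups),
                     file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ground_truth$event_map, file.path(dir, "event_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
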