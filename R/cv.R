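#' Subject-grouped k-fold assignment
#'
#' Partitions subjects (never individual steps) into `k` folds so that no
#' person's data spans training and validation. Subjects are assigned
#' greedily in descending order of sample count to the fold with the
#' fewest subjects (ties: fewest samples), which balances subject counts
#' exactly; a bounded pass of one-for-one swaps then reduces the spread
#' of the PD sample fraction across folds. Deterministic given `seed`.
#'
#' @param info tibble with one row per sample, columns `subject_id` and
#'   `label` (0/1).
#' @param k number of folds.
#' @param seed integer seed (drives the tie-shuffling of equal-count
#'   subjects).
#' @return Tibble `subject_id`, `fold` (1..k), one row per subject.
#' @export
grouped_kfold <- function(info, k = 5, seed = 1) {
  subj <- dplyr::summarise(
    dplyr::group_by(info, .data$subject_id),
    n = dplyr::n(), n_pd = sum(.data$label == 1), .groups = "drop"
  )
  if (nrow(subj) < k) {
    stop("fewer subjects (", nrow(subj), ") than folds (", k, ")", call. = FALSE)
  }
  subj <- .with_seed(seed, subj[sample.int(nrow(subj)), , drop = FALSE])
  subj <- subj[order(-subj$n), , drop = FALSE]

  fold_of <- integer(nrow(subj))
  n_subj <- integer(k)
  n_samp <- integer(k)
  for (i in seq_len(nrow(subj))) {
    target <- order(n_subj, n_samp, seq_len(k))[1]
    fold_of[i] <- target
    n_subj[target] <- n_subj[target] + 1L
    n_samp[target] <- n_samp[target] + subj$n[i]
  }

  # local swaps: one-for-one subject exchanges between folds that shrink
  # the spread of PD sample fractions (subject counts preserved)
  pd_spread <- function(f) {
    frac <- vapply(seq_len(k), function(j) {
      tot <- sum(subj$n[f == j])
      if (tot == 0) 0 else sum(subj$n_pd[f == j]) / tot
    }, numeric(1))
    sum(abs(frac - sum(subj$n_pd) / sum(subj$n)))
  }
  cur <- pd_spread(fold_of)
  for (pass in 1:2) {
    improved <- FALSE
    for (i in seq_len(nrow(subj))) {
      for (j in seq_len(nrow(subj))) {
        if (j <= i || fold_of[i] == fold_of[j]) next
        cand <- fold_of
        cand[c(i, j)] <- cand[c(j, i)]
        val <- pd_spread(cand)
        if (val < cur - 1e-12) {
          fold_of <- cand
          cur <- val
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  tibble::tibble(subject_id = subj$subject_id, fold = fold_of)[order(subj$subject_id), ]
}
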