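# Dataset construction: batches of labeled episodes with an exact,
# stratified train/test split and an on-disk manifest.

#' Generate a labeled episode dataset with a train/test split
#'
#' Generates `n_episodes` episodes (a `balance` fraction of them
#' medication-taking), assigns exactly `n_train` of them to the training
#' partition by a seeded, class-stratified shuffle, and optionally writes
#' ground truth (JSON-lines) and rendered frames (PNG) to `output_dir`.
#'
#' Stratification keeps the class balance of each partition within one
#' episode of `balance`: the training partition receives
#' `round(n_train * balance)` medication episodes.
#'
#' @param grammar An [EpisodeGrammar-class].
#' @param n_episodes Total number of episodes.
#' @param balance Fraction of medication episodes, in `(0, 1)`.
#' @param n_train Number of training episodes, `0 < n_train < n_episodes`.
#' @param seed Integer seed driving episode generation and the split.
#' @param duration_s,fps Episode length and frame rate (defaults: 20 s at
#'   12.5 fps, i.e. 250 frames).
#' @param output_dir Directory for episode files, or `NULL` to keep the
#'   dataset in memory only.
#' @param render If `TRUE` (and `output_dir` is set), also write one PNG
#'   per frame; detection-stream work never needs pixels, so the default
#'   is annotation-only.
#' @return A list with `manifest` (data frame `episode_id`, `label`,
#'   `partition`, `path`), `episodes` (named list of [Episode-class]
#'   objects), `seed` and `balance`.
#' @examples
#' ds <- makeDataset(defaultGrammar(), n_episodes = 10, n_train = 6, seed = 1)
#' table(ds$manifest$partition, ds$manifest$label)
#' @export
makeDataset <- function(grammar, n_episodes, balance = 0.5, n_train,
                        seed = 1L, duration_s = 20, fps = 12.5,
                        output_dir = NULL, render = FALSE) {
  if (n_train <= 0 || n_train >= n_episodes) {
    stop("need 0 < n_train < n_episodes", call. = FALSE)
  }
  if (balance <= 0 || balance >= 1) stop("balance must be in (0,1)", call. = FALSE)
  n_med <- round(n_episodes * balance)
  labels <- c(rep("medication", n_med),
              rep("non_medication", n_episodes - n_med))
  n_train_med <- round(n_train * balance)
  n_train_non <- n_train - n_train_med

  seeds <- derive_seeds_(seed, n_episodes + 1L)
  # stratified partition assignment via seeded shuffle within each class
  partition <- character(n_episodes)
  with_seed_(seeds[n_episodes + 1L], {
    med_idx <- which(labels == "medication")
    non_idx <- which(labels == "non_medication")
    partition[sample(med_idx)] <- rep(c("train", "test"),
                                      c(n_train_med, length(med_idx) - n_train_med))
    partition[sample(non_idx)] <- rep(c("train", "test"),
                                      c(n_train_non, length(non_idx) - n_train_non))
  })

  ids <- sprintf("ep%04d", seq_len(n_episodes))
  episodes <- vector("list", n_episodes)
  paths <- rep("", n_episodes)
  for (i in seq_len(n_episodes)) {
    ep <- sampleEpisode(grammar, labels[i], duration_s = duration_s, fps = fps,
                        seed = seeds[i], episode_id = ids[i])
    episodes[[i]] <- ep
    if (!is.null(output_dir)) {
      epdir <- file.path(output_dir, "episodes", ids[i])
      dir.create(epdir, recursive = TRUE, showWarnings = FALSE)
      writeDetectionsJSONL(groundTruth(ep), file.path(epdir, "ground_truth.jsonl"),
                           episode_id = ids[i], n_frames = nFrames(ep))
      if (render) writeEpisodeFrames(ep, epdir)
      paths[i] <- epdir
    }
  }
  names(episodes) <- ids
  manifest <- data.frame(episode_id = ids, label = labels,
                         partition = partition, path = paths,
                         stringsAsFactors = FALSE)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest, file.path(output_dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = manifest, episodes = episodes, seed = seed, balance = balance)
}

#' Split a frame-level manifest into train/test partitions
#'
#' Deterministic split of `n_records` records at a training fraction:
#' exactly `floor(n_records * train_fraction)` records are assigned to
#' the training partition via a seeded shuffle.
#'
#' @param n_records Number of records.
#' @param train_fraction Training fraction in `(0, 1)`; default 0.8.
#' @param seed Integer seed.
#' @return Character vector of length `n_records` with values `"train"`
#'   and `"test"`.
#' @examples
#' table(splitFrameManifest(50, 0.8, seed = 1))
#' @export
splitFrameManifest <- function(n_records, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0,1)", call. = FALSE)
  }
  n_train <- floor(n_records * train_fraction)
  part <- rep("test", n_records)
  with_seed_(seed, part[sample.int(n_records, n_train)] <- "train")
  part
}
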