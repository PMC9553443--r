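# Ablation harness: retrain the model along one design axis and compare
# dev entity F1.  Axes mirror the model's differentiated-input design:
# which granularities feed the encoder, distribution vs random seed,
# attention data vs white noise as the generator's main input, and fused
# condition Y vs gold labels L.

.granularity_combos <- list(
  "sentence+paragraph" = c("sentence", "paragraph"),
  "sentence+paragraph+chapter" = c("sentence", "paragraph", "chapter"),
  "char+sentence" = c("char", "sentence"),
  "char+paragraph" = c("char", "paragraph"),
  "char+sentence+paragraph" = c("char", "sentence", "paragraph"),
  "char+sentence+paragraph+chapter" = c("char", "sentence", "paragraph",
                                        "chapter")
)

#' Run a one-axis ablation comparison
#'
#' Trains one model per setting of the chosen axis (per seed) and reports
#' dev entity F1 for each.
#'
#' @param train,dev annotated corpora.
#' @param axis one of \code{"granularities"}, \code{"seed"},
#'   \code{"main_input"}, \code{"condition"}.
#' @param config base [nergan_config()].
#' @param seeds integer vector of rng seeds; results are averaged rows per
#'   setting with one row per (setting, seed).
#' @param settings optional named list overriding the axis settings (for
#'   the granularities axis, a named list of granularity subsets).
#' @return data frame with columns \code{setting}, \code{seed}, \code{P},
#'   \code{R}, \code{F1}.
#' @export
run_ablation <- function(train, dev, axis = c("granularities", "seed",
                                              "main_input", "condition"),
                         config = nergan_config(), seeds = 1L,
                         settings = NULL) {
  axis <- match.arg(axis)
  if (is.null(settings)) {
    settings <- switch(axis,
      granularities = .granularity_combos,
      seed = list(distribution = "distribution", random = "random"),
      main_input = list(attention = "attention", noise = "noise"),
      condition = list(Y = "Y", L = "L")
    )
  }
  key <- switch(axis, granularities = "granularities", seed = "seed_mode",
                main_input = "main_input", condition = "condition")
  rows <- list()
  for (nm in names(settings)) {
    for (sd in seeds) {
      args <- stats::setNames(list(settings[[nm]], as.integer(sd)),
                              c(key, "rng_seed"))
      cfg <- do.call(config_update, c(list(config), args))
      fit <- nergan(train, dev = dev, config = cfg)
      m <- fit$dev_metrics$overall
      rows[[length(rows) + 1L]] <- data.frame(
        setting = nm, seed = sd, P = unname(m["P"]), R = unname(m["R"]),
        F1 = unname(m["F1"]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Shrinking-training-corpus harness
#'
#' Retrains the model on sentence-level subsamples of the training corpus
#' and reports dev entity F1 per fraction and seed, to study stability as
#' the annotated corpus shrinks.
#'
#' @param train,dev annotated corpora.
#' @param fractions fractions of the training sentences to keep.
#' @param config base [nergan_config()].
#' @param seeds integer vector of rng seeds.
#' @return data frame with columns \code{fraction}, \code{seed}, \code{P},
#'   \code{R}, \code{F1}.
#' @export
run_scale_comparison <- function(train, dev, fractions = c(1, 0.5, 0.25),
                                 config = nergan_config(), seeds = 1L) {
  rows <- list()
  for (fr in fractions) {
    for (sd in seeds) {
      sub <- synth_subsample(train, fr, rng_seed = as.integer(sd))
      cfg <- config_update(config, rng_seed = as.integer(sd))
      fit <- nergan(sub, dev = dev, config = cfg)
      m <- fit$dev_metrics$overall
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fr, seed = sd, P = unname(m["P"]), R = unname(m["R"]),
        F1 = unname(m["F1"]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
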