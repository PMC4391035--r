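#' Run the full continuous-decoding analysis
#'
#' Convenience wrapper tying the stages together: preprocessing, global
#' synergy fit, feature standardization, cross-validated Wiener decoding,
#' full-data model fit, channel ranking and lag contributions.
#'
#' @param rec a [recording()] with kinematics and events.
#' @param config a [pipeline_config()].
#' @param projection optional spatial projection matrix (artifact removal
#'   hook).
#' @param extra_exclude additional channels to drop (e.g.
#'   [frontal_channels()] for the ocular-artifact control).
#' @param outputs `"pc"` (synergies) or `"joints"`.
#' @return an object of class `decoding_run`: `prep`, `synergy`, `result`
#'   (cross-validated accuracies), `model` (full-data Wiener fit),
#'   `ranking`, `lag_contrib`, `config`.
#' @export
run_decoding <- function(rec, config = pipeline_config(), projection = NULL,
                         extra_exclude = NULL, outputs = c("pc", "joints")) {
  outputs <- match.arg(outputs)
  prep <- preprocess_recording(rec, config, projection = projection,
                               extra_exclude = extra_exclude)
  trials <- standardize_trials(prep$trials)
  synergy <- fit_synergies(trials, retained = config$retained_pcs)
  result <- cross_validate(trials, folds = config$cv_folds, seed = config$seed,
                           outputs = outputs, retained = config$retained_pcs,
                           fold_safe = config$fold_safe, synergy = synergy)
  model <- fit_wiener(trials, outputs = "pc", synergy = synergy)
  ranking <- if (config$retained_pcs >= 3L) rank_channels(model) else NULL
  lagc <- lag_contributions(model)
  structure(list(prep = prep, synergy = synergy, result = result,
                 model = model, ranking = ranking, lag_contrib = lagc,
                 config = config),
            class = "decoding_run")
}

#' @export
print.decoding_run <- function(x, ...) {
  cat("<decoding_run>\n")
  print(x$result)
  cat(sprintf("  synergies: first %d explain %.1f%% of velocity variance\n",
              x$synergy$retained,
              100 * sum(x$synergy$variance_fractions[seq_len(x$synergy$retained)])))
  if (!is.null(x$ranking)) {
    cat("  top channels:", paste(head(x$ranking$labels_ranked, 5), collapse = ", "), "\n")
  }
  invisible(x)
}
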