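#' Fit the two-class heart-sound classifier
#'
#' Pools every training subject's MFCC frames by diagnostic class and fits
#' one Gaussian mixture per class. Prediction compares a subject's
#' frame-averaged negative log-likelihood under the two models and assigns
#' the class with the lower value.
#'
#' @param features Named list of per-subject `mfcc_matrix` objects.
#' @param labels Character vector ("PH" / "non-PH"), one per subject, in
#'   the order of `features` (or named by subject id).
#' @param n_components,covariance_mode,seed,max_iter,tol,n_restarts,ridge
#'   Passed to [fit_gmm()] for both class models.
#' @return An object of class `ph_classifier` with elements `model_ph`,
#'   `model_nonph`, `n_subjects`, `n_frames`, and `fingerprint`.
#' @seealso [predict.ph_classifier()], [cross_validate()]
#' @export
ph_classifier <- function(features, labels, n_components = 8L,
                          covariance_mode = "full", seed = 1L,
                          max_iter = 200L, tol = 1e-6, n_restarts = 3L,
                          ridge = 1e-6) {
  stopifnot(length(features) == length(labels))
  labels <- normalize_labels(labels)
  for (cls in c("PH", "non-PH"))
    if (!any(labels == cls)) stop("class absent: ", cls)
  pool <- function(cls) bind_features(features[labels == cls])
  x_ph <- pool("PH"); x_np <- pool("non-PH")
  model_ph <- fit_gmm(x_ph, n_components, covariance_mode, seed = seed,
                      max_iter = max_iter, tol = tol,
                      n_restarts = n_restarts, ridge = ridge)
  model_nonph <- fit_gmm(x_np, n_components, covariance_mode,
                         seed = seed + 1L, max_iter = max_iter, tol = tol,
                         n_restarts = n_restarts, ridge = ridge)
  structure(list(model_ph = model_ph, model_nonph = model_nonph,
                 n_subjects = c(PH = sum(labels == "PH"),
                                `non-PH` = sum(labels == "non-PH")),
                 n_frames = c(PH = nrow(x_ph$values),
                              `non-PH` = nrow(x_np$values)),
                 fingerprint = x_ph$fingerprint,
                 training_subjects = names(features) %||%
                   unlist(lapply(features, function(f) f$info$subject_id[1]))),
            class = "ph_classifier")
}

normalize_labels <- function(labels) {
  out <- ifelse(labels %in% c("PH", "ph", "1", "TRUE"), "PH", "non-PH")
  out[is.na(labels)] <- NA
  out
}

#' @export
print.ph_classifier <- function(x, ...) {
  cat("<ph_classifier> two-class GMM heart-sound classifier\n")
  cat(sprintf("  PH model:     %d components on %d frames from %d subjects\n",
              x$model_ph$n_components, x$n_frames["PH"], x$n_subjects["PH"]))
  cat(sprintf("  non-PH model: %d components on %d frames from %d subjects\n",
              x$model_nonph$n_components, x$n_frames["non-PH"],
              x$n_subjects["non-PH"]))
  invisible(x)
}

#' Score subjects with a fitted classifier
#'
#' @param object A `ph_classifier`.
#' @param newdata One `mfcc_matrix` or a (named) list of them.
#' @param ... Unused.
#' @return Data frame with one row per subject: subject_id, nll_ph,
#'   nll_nonph, nll_ratio, predicted.
#' @export
predict.ph_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "mfcc_matrix")) newdata <- list(newdata)
  rows <- lapply(seq_along(newdata), function(i) {
    sid <- names(newdata)[i] %||% NA_character_
    if (is.null(names(newdata)) || is.na(sid) || sid == "")
      sid <- newdata[[i]]$info$subject_id[1]
    classify_subject(newdata[[i]], object$model_ph, object$model_nonph,
                     subject_id = sid)
  })
  do.call(rbind, rows)
}

#' @export
summary.ph_classifier <- function(object, ...) {
  cat(sprintf("Training log-likelihoods: PH %.2f (%d iter), non-PH %.2f (%d iter)\n",
              object$model_ph$loglik, length(object$model_ph$training_log),
              object$model_nonph$loglik,
              length(object$model_nonph$training_log)))
  invisible(object)
}

#' Run the full per-subject feature pipeline
#'
#' Convenience wrapper: R/T detection, S2 extraction and MFCC computation
#' for one recording.
#'
#' @param recording A `pcg_recording` (or anything [extract_s2_segments()]
#'   accepts).
#' @param config An [mfcc_config()].
#' @param s2_segment_duration,window_frac Passed to
#'   [extract_s2_segments()].
#' @return An `mfcc_matrix`.
#' @export
subject_pipeline <- function(recording, config = mfcc_config(),
                             s2_segment_duration = 0.100,
                             window_frac = 0.30) {
  segs <- extract_s2_segments(recording,
                              s2_segment_duration = s2_segment_duration,
                              window_frac = window_frac)
  subject_features(segs, config)
}
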