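# Per-channel summary features for the light backend: mean, sd, energy
# (mean square) and dominant frequency (Hz, DC excluded). 6 channels x 4
# features = 24 columns per window.

window_features_one <- function(values, sample_rate) {
  n <- nrow(values)
  feats <- apply(values, 2, function(x) {
    spec <- Mod(fft(x))[2:(n %/% 2 + 1)]
    k <- which.max(spec) # first maximum: deterministic tie-break
    c(mean = mean(x), sd = stats::sd(x), energy = mean(x^2),
      domfreq = k * sample_rate / n)
  })
  setNames(as.vector(feats),
           as.vector(outer(rownames(feats), colnames(feats), paste, sep = "_")))
}

#' Summary features for a window set
#'
#' Computes the light backend's feature matrix: per channel the mean,
#' standard deviation, energy (mean square) and dominant non-DC frequency
#' of each window.
#'
#' @param windows A window set from [make_windows()].
#' @return A numeric matrix, one row per window, 24 named columns.
#' @export
window_features <- function(windows) {
  if (nrow(windows) == 0) {
    abort("Empty window set.", class = "panhar_bad_argument")
  }
  feats <- map(seq_len(nrow(windows)), function(i) {
    window_features_one(windows$values[[i]], windows$sample_rate[i])
  })
  do.call(rbind, feats)
}
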