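# Wavelet denoising: drop the two finest detail bands (high-frequency noise,
# most powerline content at 360 Hz) and the coarsest approximation (baseline
# wander / DC). No coefficient thresholding inside the kept bands.

#' Denoise an ECG record by wavelet component removal
#'
#' Decomposes the record and reconstructs it from all components except D1,
#' D2 and the final approximation. At 360 Hz with 10 levels this removes
#' content above ~45 Hz and below ~0.18 Hz while leaving the QRS band
#' (D3--D5, ~5.6--45 Hz) untouched.
#'
#' @param x An [ecg_record()] or numeric vector.
#' @param spec A [wavelet_spec()]; depths below 10 are accepted with a
#'   warning that the final approximation then spans a wider low band.
#' @param decomp Optionally, a precomputed decomposition of `x` (avoids
#'   repeating the transform when the decomposition is reused downstream).
#' @return Numeric vector, the denoised signal, same length as the input.
#' @export
#' @examples
#' rec <- generate_ecg(synthesis_config(duration_s = 10, seed = 1))$record
#' den <- denoise_ecg(rec)
denoise_ecg <- function(x, spec = wavelet_spec(), decomp = NULL) {
  if (is.null(decomp)) decomp <- dwt_decompose(x, spec)
  L <- decomp$spec$levels
  if (L < 10L) {
    warning(sprintf(
      "decomposition depth %d < 10: A%d plays the baseline-wander role", L, L))
  }
  drop <- c("D1", "D2", paste0("A", L))
  keep <- setdiff(dwt_components(decomp), drop)
  dwt_reconstruct(decomp, keep)
}
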