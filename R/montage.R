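#' Standard 10-20 scalp montage with mastoids
#'
#' Returns the 19 scalp electrode labels of the international 10-20 system,
#' optionally together with the two mastoid labels (`M1`, `M2`) used for
#' offline re-referencing.
#'
#' @param mastoids logical; append the two mastoid labels.
#' @return character vector of channel labels.
#' @export
#' @examples
#' standard_montage()
standard_montage <- function(mastoids = FALSE) {
  scalp <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "O2"
  )
  if (mastoids) c(scalp, "M1", "M2") else scalp
}

#' @rdname standard_montage
#' @export
mastoid_labels <- function() c("M1", "M2")
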