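#' The ion-target registry
#'
#' Reads a registry of ion targets from a CSV config file
#' (\code{name,target_mz,tolerance_da,formula,charge}). The default registry
#' shipped with the package holds the four channels of the lung-distribution
#' assay: the GirP-derivatized budesonide cation (564.308 m/z, 0.005 Da
#' window), the derivatized triamcinolone acetonide internal standard
#' (568.283 m/z, 0.005 Da), the heme b tissue marker (616.176 m/z, 0.005 Da)
#' and the porcine SP-C ion (4188 m/z, 1 Da window; stored as an opaque m/z
#' without formula). Entries with a formula are cross-checked against
#' \code{\link{monoisotopicMass}} on construction.
#'
#' @param path path to a registry CSV; default is the shipped registry.
#' @return Named list of \linkS4class{IonTarget} objects.
#' @examples
#' reg <- ionTargetRegistry()
#' reg$heme
#' @export
ionTargetRegistry <- function(path = system.file("extdata",
                                                 "ion_targets.csv",
                                                 package = "msiSpatial")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "target_mz", "tolerance_da")
  if (!all(need %in% names(df)))
    stop("registry file must have columns ", paste(need, collapse = ", "))
  targets <- lapply(seq_len(nrow(df)), function(i) {
    f <- df$formula[i]
    f <- if (is.null(f) || is.na(f) || !nzchar(f)) NA_character_ else f
    ch <- df$charge[i]
    ch <- if (is.null(ch) || is.na(ch)) 1 else ch
    IonTarget(df$name[i], df$target_mz[i], df$tolerance_da[i],
              formula = f, charge = ch)
  })
  stats::setNames(targets, df$name)
}
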