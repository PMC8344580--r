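#' @import methods
NULL

#' Issue (or look up) a de-identified surrogate identifier
#'
#' @param store a [HIDKeyStore-class] object.
#' @param family identifier family, one of `"patient"`, `"case"`, `"image"`.
#' @param originalId the original identifier (MRN, accession number or
#'   vendor image ID).
#' @return the HID as a character scalar, e.g. `"P-9f3a01c2"`.
#' @export
setGeneric("assignHid", function(store, family, originalId)
  standardGeneric("assignHid"))

#' Recover the original identifier behind a HID
#'
#' @param store a [HIDKeyStore-class] object.
#' @param hid a de-identified identifier previously issued by [assignHid()].
#' @return the original identifier (character scalar); errors if unknown.
#' @export
setGeneric("reidentify", function(store, hid) standardGeneric("reidentify"))

#' Remove label and macro sub-images from a whole-slide image
#'
#' @param container a [WSIContainer-class].
#' @param outPath path for the de-identified copy (in-place editing is
#'   refused; the output is always a new file).
#' @return a [WSIContainer-class] parsed from the written output file.
#' @export
setGeneric("stripAssociatedImages", function(container, outPath)
  standardGeneric("stripAssociatedImages"))

#' Mask sensitive metadata values in a whole-slide image
#'
#' @param container a [WSIContainer-class].
#' @param policy a [SensitiveFieldPolicy-class] naming the description keys
#'   whose values are overwritten.
#' @param outPath path for the scrubbed copy.
#' @return a [WSIContainer-class] parsed from the written output file.
#' @export
setGeneric("scrubMetadata", function(container, policy, outPath)
  standardGeneric("scrubMetadata"))

#' Screen a whole-slide image for dark label-sticker bleed-through
#'
#' @param x a [WSIContainer-class] (or an RGB pixel array for the low-level
#'   method).
#' @param params a [DarkRegionParams-class].
#' @param imageId identifier recorded in the decision (defaults to the
#'   container's source path).
#' @return a [ScreenDecision-class].
#' @export
setGeneric("screenWSI", function(x, params = darkRegionParams(), imageId = NULL)
  standardGeneric("screenWSI"))
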