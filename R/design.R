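#' Construct an NCII mating design
#'
#' Builds the cross map of a North Carolina design II: every male crossed
#' with every female (full factorial) unless an explicit `crosses` table
#' is supplied.
#'
#' @param maleIds,femaleIds character vectors of parent ids (disjoint).
#' @param repLabels replication/block labels (default `"rep1"..."rep3"`,
#'   the usual three-replicate field layout).
#' @param crosses optional data.frame (`male`, `female`, `hybrid`) for an
#'   incomplete design; if `NULL` the full factorial is generated with
#'   hybrid ids `male x female`.
#' @return An [NCIIDesign-class] object.
#' @examples
#' d <- nciiDesign(c("m1", "m2"), c("f1", "f2"))
#' crossMap(d)
#' @export
nciiDesign <- function(maleIds, femaleIds,
                       repLabels = paste0("rep", 1:3), crosses = NULL) {
  maleIds <- as.character(maleIds)
  femaleIds <- as.character(femaleIds)
  complete <- is.null(crosses)
  if (is.null(crosses)) {
    crosses <- expand.grid(male = maleIds, female = femaleIds,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    crosses$hybrid <- paste0(crosses$male, "x", crosses$female)
  } else {
    crosses <- as.data.frame(crosses, stringsAsFactors = FALSE)
    complete <- nrow(crosses) == length(maleIds) * length(femaleIds) &&
      !anyDuplicated(paste(crosses$male, crosses$female))
  }
  new("NCIIDesign", maleIds = maleIds, femaleIds = femaleIds,
      crosses = crosses, repLabels = as.character(repLabels),
      complete = complete)
}

#' @describeIn nciiDesign the cross map (male, female, hybrid)
#' @param x an `NCIIDesign`
#' @export
crossMap <- function(x) x@crosses

#' @describeIn nciiDesign male parent ids
#' @export
maleIds <- function(x) x@maleIds

#' @describeIn nciiDesign female parent ids
#' @export
femaleIds <- function(x) x@femaleIds

#' @describeIn nciiDesign replication labels
#' @export
repLabels <- function(x) x@repLabels

#' @export
setMethod("show", "NCIIDesign", function(object) {
  cat("NCIIDesign:", length(object@maleIds), "males x",
      length(object@femaleIds), "females,",
      nrow(object@crosses), "crosses,",
      length(object@repLabels), "replications",
      if (object@complete) "(complete factorial)" else "(incomplete)", "\n")
})
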