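#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

# Limb identifiers, in registry order (front-right, front-left, back-right,
# back-left).  Marker numbering within a limb runs proximal (1) -> distal (5).
LIMBS <- c("FR", "FL", "BR", "BL")

# Marker index within a limb used as the "girdle" anchor of the limb phase
# signal: greater tubercle of the humerus (front) / greater trochanter of the
# femur (back), and as the distal paw marker.
GIRDLE_IDX <- 2L
PAW_IDX <- 5L

#' Canonical 25-marker set
#'
#' The marker set consists of five markers per limb, numbered proximal to
#' distal (`FR1`..`FR5`, `FL1`..`FL5`, `BR1`..`BR5`, `BL1`..`BL5`), and five
#' axial markers: occipital protuberance (`S1`), dorsal spinous processes of
#' vertebrae `T1`, `T13` and `L7`, and the sacral apex (`S5`).
#'
#' @return Character vector of the 25 marker labels, in canonical order.
#'   The anatomical role of each marker is attached as the `"roles"`
#'   attribute (named character vector).
#' @export
#' @examples
#' canonical_markers()
canonical_markers <- function() {
  limb_roles <- list(
    F = c("dorsal aspect of the scapular spine",
          "greater tubercle of the humerus",
          "lateral epicondyle of the humerus",
          "ulnar styloid process",
          "distal lateral aspect of the fifth metacarpal bone"),
    B = c("iliac crest",
          "greater trochanter of the femur",
          "lateral femoral condyle",
          "lateral malleolus of the fibula",
          "distal lateral aspect of the fifth metatarsal bone")
  )
  labels <- character(0)
  roles <- character(0)
  for (limb in LIMBS) {
    lab <- paste0(limb, 1:5)
    labels <- c(labels, lab)
    roles <- c(roles, stats::setNames(limb_roles[[substr(limb, 1, 1)]], lab))
  }
  axial <- c(S1 = "occipital protuberance",
             T1 = "dorsal spinous process of vertebra T1",
             T13 = "dorsal spinous process of vertebra T13",
             L7 = "dorsal spinous process of vertebra L7",
             S5 = "sacral apex")
  labels <- c(labels, names(axial))
  roles <- c(roles, axial)
  structure(labels, roles = roles)
}

#' Markers belonging to one limb
#'
#' @param limb One of `"FR"`, `"FL"`, `"BR"`, `"BL"`.
#' @return Character vector of the limb's five marker labels, proximal to
#'   distal.
#' @export
limb_markers <- function(limb) {
  limb <- match.arg(limb, LIMBS)
  paste0(limb, 1:5)
}

#' Axis mapping between an export frame and the canonical frame
#'
#' The canonical frame is: `x` positive toward the animal's cranial
#' direction, `y` positive toward its left, `z` vertical up (right-handed).
#' An export whose axes differ is described by a three-letter string giving,
#' for canonical x, y and z in order, the source axis that supplies it, each
#' optionally preceded by `-` to flip the sign.  `"xyz"` is the identity;
#' `"y-xz"` means canonical x = source y, canonical y = -(source x),
#' canonical z = source z.
#'
#' @param spec Mapping string as described above.
#' @return An `axis_mapping` object: a list with integer `perm` (source axis
#'   index per canonical axis) and numeric `sign`.
#' @export
#' @examples
#' m <- axis_mapping("y-xz")
#' apply_axis_mapping(matrix(c(1, 2, 3), 1), m)
axis_mapping <- function(spec = "xyz") {
  if (!is.character(spec) || length(spec) != 1L)
    stop("axis mapping spec must be a single string such as \"xyz\" or \"z-xy\"")
  toks <- regmatches(spec, gregexpr("-?[xyz]", spec))[[1]]
  if (length(toks) != 3L || sum(nchar(toks)) != nchar(spec))
    stop("malformed axis mapping: ", spec)
  axis_chr <- sub("^-", "", toks)
  perm <- match(axis_chr, c("x", "y", "z"))
  if (anyNA(perm) || anyDuplicated(perm))
    stop("axis mapping must use each of x, y, z exactly once: ", spec)
  sign <- ifelse(startsWith(toks, "-"), -1, 1)
  # right-handedness: determinant of the signed permutation must be +1
  mat <- matrix(0, 3, 3)
  mat[cbind(1:3, perm)] <- sign
  if (det(mat) < 0)
    stop("axis mapping ", spec, " is left-handed; flip one sign")
  structure(list(spec = spec, perm = perm, sign = sign), class = "axis_mapping")
}

#' @rdname axis_mapping
#' @param xyz An n x 3 coordinate matrix in the source frame.
#' @param mapping An `axis_mapping`.
#' @export
apply_axis_mapping <- function(xyz, mapping) {
  stopifnot(inherits(mapping, "axis_mapping"), ncol(xyz) == 3L)
  out <- xyz[, mapping$perm, drop = FALSE]
  out <- sweep(out, 2, mapping$sign, `*`)
  colnames(out) <- c("x", "y", "z")
  out
}

#' @rdname axis_mapping
#' @export
invert_axis_mapping <- function(mapping) {
  stopifnot(inherits(mapping, "axis_mapping"))
  perm <- order(mapping$perm)
  sign <- mapping$sign[perm]
  chr <- c("x", "y", "z")[perm]
  spec <- paste0(ifelse(sign < 0, "-", ""), chr, collapse = "")
  axis_mapping(spec)
}
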