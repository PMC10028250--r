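#' Canonical landmark set
#'
#' The 17 points of interest digitized on a laterally filmed piglet:
#' head (snout, eye, ear), back line (withers, croup, tailbase), forelimb
#' (scapula, shoulder, elbow, carpal, forefetlock, forehoof) and hindlimb
#' (hip, stifle, tarsal, hindfetlock, hindhoof).
#'
#' @return Character vector of the 17 canonical landmark names, in order.
#' @export
landmark_names <- function() {
  c("snout", "eye", "ear",
    "withers", "croup", "tailbase",
    "scapula", "shoulder", "elbow", "carpal", "forefetlock", "forehoof",
    "hip", "stifle", "tarsal", "hindfetlock", "hindhoof")
}

#' Skeleton segments connecting the canonical landmarks
#'
#' Segment list used for bone-length plausibility filtering, the size PCA
#' and the snout-to-tailbase reference chain: head chain, back line,
#' forelimb chain and hindlimb chain.
#'
#' @return data.frame with columns `from`, `to` (landmark names) and
#'   `segment` (label "from-to").
#' @export
skeleton_segments <- function() {
  seg <- rbind(
    c("snout", "eye"), c("eye", "ear"), c("ear", "withers"),
    c("withers", "croup"), c("croup", "tailbase"),
    c("withers", "scapula"), c("scapula", "shoulder"),
    c("shoulder", "elbow"), c("elbow", "carpal"),
    c("carpal", "forefetlock"), c("forefetlock", "forehoof"),
    c("croup", "hip"), c("hip", "stifle"), c("stifle", "tarsal"),
    c("tarsal", "hindfetlock"), c("hindfetlock", "hindhoof"))
  data.frame(from = seg[, 1], to = seg[, 2],
             segment = paste(seg[, 1], seg[, 2], sep = "-"))
}

#' Joint definitions as landmark triples
#'
#' Each joint angle is measured between the extension of the
#' proximal->center segment and the center->distal segment: a straight
#' (fully extended) joint is zero, counter-clockwise angles are positive.
#' The six analysis joints are shoulder, elbow, carpal (forelimb) and hip,
#' stifle, tarsal (hindlimb); `forelimb_total` (croup-withers-forehoof) is
#' the phase reference for temporal alignment and does not itself enter
#' the analysis.
#'
#' @return data.frame with columns `joint`, `proximal`, `center`, `distal`.
#' @export
joint_definitions <- function() {
  data.frame(
    joint    = c("shoulder", "elbow", "carpal", "hip", "stifle", "tarsal",
                 "forelimb_total"),
    proximal = c("scapula", "shoulder", "elbow", "croup", "hip", "stifle",
                 "croup"),
    center   = c("shoulder", "elbow", "carpal", "hip", "stifle", "tarsal",
                 "withers"),
    distal   = c("elbow", "carpal", "forefetlock", "stifle", "tarsal",
                 "hindfetlock", "forehoof"))
}

#' @rdname joint_definitions
#' @export
analysis_joints <- function() {
  c("shoulder", "elbow", "carpal", "hip", "stifle", "tarsal")
}

# landmark chain whose cumulated segment distances give the dimensionless
# reference length (snout-to-tailbase line along the body)
reference_chain <- function() {
  c("snout", "eye", "ear", "withers", "croup", "tailbase")
}
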