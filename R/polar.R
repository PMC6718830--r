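# Polar / cylindrical "three-way volcano" projection: maps per-gene group
# means for the three pathotypes onto two dimensions analogously to an
# RGB -> HSV colour-space conversion, with -log10 likelihood-ratio p as
# the cylinder height.

#' Colour-class hex map for plot payloads
#'
#' Fixed hex values so serialized payloads are bit-reproducible; override
#' by passing a modified copy to the payload builders.
#' @export
pathotype_colors <- c(
  blue = "#0000FF", red = "#FF0000", green = "#00B050",
  purple = "#A000A0", yellow = "#FFC000", cyan = "#00B0F0",
  gray = "#808080")

P_UNDERFLOW <- 1e-300   # -log10 cap at 300 for p-value underflow

#' Project three group means onto polar coordinates
#'
#' Maps the per-gene triple of group means (lymphoid L, myeloid M, fibroid
#' F) onto the horizontal plane by
#' `x = sqrt(3)/2 * (M - F)`, `y = L - (M + F)/2`, with polar angle
#' `theta = atan2(y, x)` (reported in degrees in \[0, 360); defined as 0 at
#' the origin) and radius `r = sqrt(x^2 + y^2)`. The three pathotype axes
#' land at L = 90 deg, M = 330 deg, F = 210 deg. The height
#' `z_height = -log10(lrt_p)`, with p clipped at 1e-300. Adding a constant
#' to all three means leaves (x, y) unchanged.
#'
#' @param L,M,F Numeric vectors of group means (Z scores or log folds).
#' @param lrt_p Likelihood-ratio p values in (0, 1\] (0 is clipped).
#' @param gene_id Optional gene identifiers.
#' @param color_class Optional colour classes carried through.
#' @return data.frame with columns `gene_id`, `L`, `M`, `F`, `x`, `y`,
#'   `theta_deg`, `r`, `z_height`, and `color_class` if supplied.
#' @export
polar_project <- function(L, M, F, lrt_p, gene_id = NULL,
                          color_class = NULL) {
  if (!all(is.finite(L), is.finite(M), is.finite(F)))
    stopf("group means must be finite")
  if (any(is.na(lrt_p)) || any(lrt_p < 0 | lrt_p > 1))
    stopf("lrt_p must lie in [0, 1]")
  x <- sqrt(3) / 2 * (M - F)
  y <- L - (M + F) / 2
  theta <- atan2(y, x) * 180 / pi
  theta <- theta %% 360
  theta[x == 0 & y == 0] <- 0
  r <- sqrt(x^2 + y^2)
  z <- -log10(pmax(lrt_p, P_UNDERFLOW))
  out <- data.frame(
    gene_id = gene_id %||% paste0("gene", seq_along(L)),
    L = L, M = M, F = F, x = x, y = y, theta_deg = theta, r = r,
    z_height = z, stringsAsFactors = FALSE)
  if (!is.null(color_class)) out$color_class <- color_class
  out
}

#' Build the polar payload from a differential-expression table
#'
#' Converts a [run_threeway_de()] result into the gene table of polar
#' coordinates plus axis annotations. With `radial_mode = "zscore"` the
#' radial scale uses the per-group mean Z scores; with `"fold"` it uses the
#' per-group log2 fold changes versus the per-gene minimum-mean reference.
#' The polar angle is recomputed from whichever triple is used, so the two
#' modes agree exactly only when fold changes are proportional to centred Z
#' differences; the payload reports the radial mode used.
#'
#' @param de data.frame from [run_threeway_de()].
#' @param radial_mode `"zscore"` (default) or `"fold"`.
#' @param q_threshold Significance threshold recorded in the payload.
#' @return List of class `"polar_payload"` with elements `genes` (the
#'   [polar_project()] table), `axes` (L/M/F angles, 120 degrees apart),
#'   `radial_mode` and `q_threshold`.
#' @export
build_payload <- function(de, radial_mode = c("zscore", "fold"),
                          q_threshold = NULL) {
  radial_mode <- match.arg(radial_mode)
  if (!nrow(de)) stopf("empty differential-expression table")
  if (radial_mode == "zscore") {
    L <- de$z_lymphoid; M <- de$z_myeloid; F <- de$z_fibroid
  } else {
    L <- de$log2fc_lymphoid; M <- de$log2fc_myeloid; F <- de$log2fc_fibroid
  }
  p <- de$lrt_p
  p[is.na(p)] <- 1
  genes <- polar_project(L, M, F, p, gene_id = de$gene_id,
                         color_class = de$color_class)
  structure(list(
    genes = genes,
    axes = data.frame(group = c("lymphoid", "myeloid", "fibroid"),
                      angle_deg = c(90, 330, 210), stringsAsFactors = FALSE),
    radial_mode = radial_mode,
    q_threshold = q_threshold %||% attr(de, "q_threshold") %||% 0.05),
    class = "polar_payload")
}

#' Serializable 2D polar plot structure
#'
#' @param payload A `"polar_payload"` from [build_payload()].
#' @param colors Named class -> hex map (default [pathotype_colors]).
#' @return JSON-ready list: `points` (gene, x, y, theta_deg, r, color hex),
#'   `axes` with guide angles, and plot metadata. No plotting library is
#'   needed to validate it.
#' @export
polar_2d_payload <- function(payload, colors = pathotype_colors) {
  stopifnot(inherits(payload, "polar_payload"))
  g <- payload$genes
  cls <- if ("color_class" %in% names(g)) g$color_class else "gray"
  list(
    type = "polar2d",
    radial_mode = payload$radial_mode,
    axes = payload$axes,
    points = data.frame(
      gene_id = g$gene_id, x = g$x, y = g$y, theta_deg = g$theta_deg,
      r = g$r, color = unname(colors[cls]), stringsAsFactors = FALSE))
}

#' Serializable 3D cylindrical volcano structure
#'
#' @inheritParams polar_2d_payload
#' @return JSON-ready list with `points` carrying `z` = -log10 LRT p
#'   (clipped at 300) in addition to the planar coordinates.
#' @export
cylinder_3d_payload <- function(payload, colors = pathotype_colors) {
  out <- polar_2d_payload(payload, colors)
  out$type <- "cylinder3d"
  out$points$z <- payload$genes$z_height
  out$z_label <- "-log10 LRT p"
  out
}
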