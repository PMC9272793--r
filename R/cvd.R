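# Color-vision-deficiency simulation.
#
# Severity-parameterized 3x3 simulation matrices from Machado, Oliveira &
# Fernandes (2009), "A Physiologically-based Model for Simulation of Color
# Vision Deficiency", IEEE TVCG 15(6):1291-1298, tabulated at severity steps
# 0.0, 0.1, ..., 1.0. The matrices operate on linear-light RGB; severity 0
# is the identity. Stored row-major.

.machado <- list(
  protan = list(
    c(1.000000, 0.000000, 0.000000, 0.000000, 1.000000, 0.000000, 0.000000, 0.000000, 1.000000),
    c(0.856167, 0.182038, -0.038205, 0.029342, 0.955115, 0.015544, -0.002880, -0.001563, 1.004443),
    c(0.734766, 0.334872, -0.069637, 0.051840, 0.919198, 0.028963, -0.004928, -0.004209, 1.009137),
    c(0.630323, 0.465641, -0.095964, 0.069181, 0.890046, 0.040773, -0.006308, -0.007724, 1.014032),
    c(0.539009, 0.579343, -0.118352, 0.082546, 0.866121, 0.051332, -0.007136, -0.011959, 1.019095),
    c(0.458064, 0.679578, -0.137642, 0.092785, 0.846313, 0.060902, -0.007494, -0.016807, 1.024301),
    c(0.385450, 0.769005, -0.154455, 0.100526, 0.829802, 0.069673, -0.007442, -0.022190, 1.029632),
    c(0.319627, 0.849633, -0.169261, 0.106241, 0.815969, 0.077790, -0.007025, -0.028051, 1.035076),
    c(0.259411, 0.923008, -0.182420, 0.110296, 0.804340, 0.085364, -0.006276, -0.034346, 1.040622),
    c(0.203876, 0.990338, -0.194214, 0.112975, 0.794542, 0.092483, -0.005222, -0.041043, 1.046265),
    c(0.152286, 1.052583, -0.204868, 0.114503, 0.786281, 0.099216, -0.003882, -0.048116, 1.051998)
  ),
  deutan = list(
    c(1.000000, 0.000000, 0.000000, 0.000000, 1.000000, 0.000000, 0.000000, 0.000000, 1.000000),
    c(0.866435, 0.177704, -0.044139, 0.049567, 0.939063, 0.011370, -0.003453, 0.007233, 0.996220),
    c(0.760729, 0.319078, -0.079807, 0.090568, 0.889315, 0.020117, -0.006027, 0.013325, 0.992702),
    c(0.675425, 0.433850, -0.109275, 0.125303, 0.847755, 0.026942, -0.007950, 0.018572, 0.989378),
    c(0.605511, 0.528560, -0.134071, 0.155318, 0.812366, 0.032316, -0.009376, 0.023176, 0.986200),
    c(0.547494, 0.607765, -0.155259, 0.181692, 0.781742, 0.036566, -0.010410, 0.027275, 0.983136),
    c(0.498864, 0.674741, -0.173604, 0.205199, 0.754872, 0.039929, -0.011131, 0.030969, 0.980162),
    c(0.457771, 0.731899, -0.189670, 0.226409, 0.731012, 0.042579, -0.011595, 0.034333, 0.977261),
    c(0.422823, 0.781057, -0.203881, 0.245752, 0.709602, 0.044646, -0.011843, 0.037423, 0.974421),
    c(0.392952, 0.823610, -0.216562, 0.263559, 0.690210, 0.046232, -0.011910, 0.040281, 0.971630),
    c(0.367322, 0.860646, -0.227968, 0.280085, 0.672501, 0.047413, -0.011820, 0.042940, 0.968881)
  ),
  tritan = list(
    c(1.000000, 0.000000, 0.000000, 0.000000, 1.000000, 0.000000, 0.000000, 0.000000, 1.000000),
    c(0.926670, 0.092514, -0.019184, 0.021191, 0.964503, 0.014306, 0.008437, 0.054813, 0.936750),
    c(0.895720, 0.133330, -0.029050, 0.029997, 0.945400, 0.024603, 0.013027, 0.104707, 0.882266),
    c(0.905871, 0.127791, -0.033662, 0.026856, 0.941251, 0.031893, 0.013410, 0.148296, 0.838294),
    c(0.948035, 0.089490, -0.037526, 0.014364, 0.946792, 0.038844, 0.010853, 0.193991, 0.795156),
    c(1.017277, 0.027029, -0.044306, -0.006113, 0.958479, 0.047634, 0.006379, 0.248708, 0.744913),
    c(1.104996, -0.046633, -0.058363, -0.032137, 0.971635, 0.060503, 0.001336, 0.317922, 0.680742),
    c(1.193214, -0.109812, -0.083402, -0.058496, 0.979410, 0.079086, -0.002346, 0.403492, 0.598854),
    c(1.257728, -0.139648, -0.118081, -0.078003, 0.975409, 0.102594, -0.003316, 0.501214, 0.502102),
    c(1.278864, -0.125333, -0.153531, -0.084748, 0.957674, 0.127074, -0.000989, 0.601151, 0.399838),
    c(1.255528, -0.076749, -0.178779, -0.078411, 0.930809, 0.147602, 0.004733, 0.691367, 0.303900)
  )
)

#' CVD simulation matrix for a deficiency type and severity
#'
#' Returns the 3x3 linear-RGB simulation matrix for protan, deutan or tritan
#' color vision at a given severity, interpolating linearly between the
#' tabulated Machado et al. (2009) severity steps (0.1 apart). Severity 0
#' (and `kind = "none"`) gives the identity.
#'
#' @param kind One of `"none"`, `"protan"`, `"deutan"`, `"tritan"`.
#' @param severity Severity on \[0, 1\]; default 1 (dichromacy).
#' @return A 3x3 numeric matrix acting on linear-RGB column vectors.
#' @examples
#' cvd_matrix("deutan", severity = 1)
#' @export
cvd_matrix <- function(kind = c("none", "protan", "deutan", "tritan"),
                       severity = 1) {
  kind <- match.arg(kind)
  if (!is.numeric(severity) || length(severity) != 1 || is.na(severity) ||
      severity < 0 || severity > 1) {
    stop("`severity` must be a single number in [0, 1]", call. = FALSE)
  }
  if (kind == "none" || severity == 0) {
    return(diag(3))
  }
  steps <- .machado[[kind]]
  pos <- severity * 10
  lo <- floor(pos)
  hi <- ceiling(pos)
  m_lo <- matrix(steps[[lo + 1]], 3, 3, byrow = TRUE)
  if (hi == lo) return(m_lo)
  m_hi <- matrix(steps[[hi + 1]], 3, 3, byrow = TRUE)
  (hi - pos) * m_lo + (pos - lo) * m_hi
}

# sRGB transfer functions (IEC 61966-2-1): gamma-encoded <-> linear light.
srgb_decode <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

#' Simulate color-vision deficiency for a palette
#'
#' Transforms RGB colors to approximate how they appear to a viewer with
#' protanopia, deuteranopia or tritanopia (or the corresponding anomalous
#' trichromacies at `severity < 1`). Channels are decoded from sRGB to
#' linear light, multiplied by the Machado et al. (2009) simulation matrix
#' ([cvd_matrix()]), clipped to \[0, 1\] and re-encoded. `kind = "none"` or
#' `severity = 0` returns the input unchanged.
#'
#' @param colors A color table from [parse_palette()] (columns `hex`, `r`,
#'   `g`, `b`), or any data frame with `r`, `g`, `b` on \[0, 1\].
#' @param cvd Deficiency type: `"none"`, `"protan"`, `"deutan"`, `"tritan"`.
#' @param severity Severity on \[0, 1\], default 1.
#' @return A tibble of the same shape with transformed `r`, `g`, `b`; the
#'   `hex` column (if present) keeps the original source strings.
#' @examples
#' simulate_cvd(parse_palette(c("#FF0000", "#00FF00")), cvd = "deutan")
#' @export
simulate_cvd <- function(colors, cvd = c("none", "protan", "deutan", "tritan"),
                         severity = 1) {
  cvd <- match.arg(cvd)
  colors <- check_colors(colors)
  if (cvd == "none" || severity == 0) {
    return(colors)
  }
  m <- cvd_matrix(cvd, severity)
  lin <- srgb_decode(t(as.matrix(colors[, c("r", "g", "b")])))
  sim <- pmin(pmax(m %*% lin, 0), 1)
  out <- srgb_encode(t(sim))
  colors$r <- out[, 1]
  colors$g <- out[, 2]
  colors$b <- out[, 3]
  colors
}
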