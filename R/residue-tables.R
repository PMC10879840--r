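## Physicochemical residue tables used by the divergence and supertype stages.

## Grantham's (1974) composition (c), polarity (p) and molecular volume (v)
## for the 20 standard amino acids.
.grantham_props <- data.frame(
  row.names = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
  c = c(1.42, 0.65, 0.00, 0.39, 0.71, 0.00, 0.00, 0.74, 0.00, 0.00,
        0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0.00, 0.13),
  p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
        6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
  v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
        136, 55, 96, 85, 56, 119, 54, 83, 105, 170))

## Weights of the three property terms (Grantham 1974).
.grantham_weights <- c(alpha = 1.833, beta = 0.1018, gamma = 0.000399)

## Sandberg et al. (1998) z1-z5 descriptor scales: lipophilicity, steric
## bulk/polarizability, polarity, and two electronic-property scales. Used to
## describe residues at positively selected sites for supertype clustering.
.zscales <- matrix(c(
  0.24, -2.32,  0.60, -0.14,  1.30,   # A
  3.52,  2.50, -3.50,  1.99, -0.17,   # R
  3.05,  1.62,  1.04, -1.15,  1.61,   # N
  3.98,  0.93,  1.93, -2.46,  0.75,   # D
  0.84, -1.67,  3.71,  0.18, -2.65,   # C
  1.75,  0.50, -1.44, -1.34,  0.66,   # Q
  3.11,  0.26, -0.11, -3.04, -0.25,   # E
  2.05, -4.06,  0.36, -0.82, -0.38,   # G
  2.47,  1.95,  0.26,  3.90,  0.09,   # H
 -3.89, -1.73, -1.71, -0.84,  0.26,   # I
 -4.28, -1.30, -1.49, -0.72,  0.84,   # L
  2.29,  0.89, -2.49,  1.49,  0.31,   # K
 -2.85, -0.22,  0.47,  1.94, -0.98,   # M
 -4.22,  1.94,  1.06,  0.54, -0.62,   # F
 -1.66,  0.27,  1.84,  0.70,  2.00,   # P
  2.39, -1.07,  1.15, -1.39,  0.67,   # S
  0.75, -2.18, -1.12, -1.46, -0.40,   # T
 -4.36,  3.94,  0.59,  3.44, -1.59,   # W
 -2.54,  2.44,  0.43,  0.04, -1.47,   # Y
 -2.59, -2.64, -1.54, -0.85, -0.02),  # V
  ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                  paste0("z", 1:5)))

## Scaled so that the mean over the 190 unordered residue pairs is 100
## (Grantham's convention); cached after first computation.
.grantham_env <- new.env(parent = emptyenv())

#' Grantham distance matrix
#'
#' The full 20 x 20 matrix of Grantham (1974) physicochemical distances,
#' computed from residue composition, polarity and molecular volume as
#' `rho * sqrt(alpha*dc^2 + beta*dp^2 + gamma*dv^2)`, with `rho` fixed so the
#' mean over all 190 unordered residue pairs equals 100.
#'
#' @return A symmetric numeric matrix with zero diagonal, dimnames the
#'   one-letter residue codes.
#' @examples
#' m <- grantham_matrix()
#' m["L", "S"]   # ~145 in Grantham's published (rounded) table
#' @export
grantham_matrix <- function() {
  if (!is.null(.grantham_env$mat)) return(.grantham_env$mat)
  pr <- .grantham_props
  w <- .grantham_weights
  res <- rownames(pr)
  raw <- outer(seq_along(res), seq_along(res), function(i, j) {
    sqrt(w["alpha"] * (pr$c[i] - pr$c[j])^2 +
         w["beta"]  * (pr$p[i] - pr$p[j])^2 +
         w["gamma"] * (pr$v[i] - pr$v[j])^2)
  })
  rho <- 100 / mean(raw[upper.tri(raw)])
  mat <- rho * raw
  dimnames(mat) <- list(res, res)
  .grantham_env$mat <- mat
  mat
}

#' Residue z-scale descriptors
#'
#' Five physicochemical descriptor values (Sandberg et al. z-scales) per
#' standard amino acid, the substrate for supertype clustering.
#'
#' @return A 20 x 5 numeric matrix, rows named by one-letter residue code.
#' @export
zscale_table <- function() .zscales
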