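#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   bind_rows left_join distinct across n row_number pull rename
#' @importFrom rlang .data
NULL

# unit-normalize a 3-vector
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("Cannot normalize a (near-)zero vector.")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of vector v by angle (radians) about unit axis k
rotate_about <- function(v, k, angle) {
  k <- unit(k)
  v * cos(angle) + cross3(k, v) * sin(angle) + k * sum(k * v) * (1 - cos(angle))
}

# 3x3 rotation matrix from Euler angles (radians), applied as Rz %*% Ry %*% Rx
euler_matrix <- function(ax = 0, ay = 0, az = 0) {
  rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

#' Parse a residue selector of the form "chain:resno"
#'
#' @param x A string such as `"A:194"`, or a list with elements `chain` and
#'   `resno` (returned unchanged).
#' @return A list with elements `chain` (character) and `resno` (integer).
#' @export
parse_residue_selector <- function(x) {
  if (is.list(x) && all(c("chain", "resno") %in% names(x))) {
    return(list(chain = as.character(x$chain), resno = as.integer(x$resno)))
  }
  if (!is.character(x) || length(x) != 1 || !grepl(":", x, fixed = TRUE)) {
    abort("Residue selector must be a \"chain:resno\" string, e.g. \"A:194\".")
  }
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  list(chain = parts[1], resno = as.integer(parts[2]))
}

# linear interpolation with a hard range check
interp_checked <- function(x, y, xout, what = "value") {
  if (any(xout < min(x) | xout > max(x))) {
    abort(sprintf("Requested %s at %s outside the tabulated range [%g, %g].",
                  what, paste(signif(xout[xout < min(x) | xout > max(x)], 5),
                              collapse = ", "),
                  min(x), max(x)))
  }
  stats::approx(x, y, xout = xout, ties = "ordered")$y
}

gas_constant_kj <- 8.314462618e-3  # kJ mol^-1 K^-1
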