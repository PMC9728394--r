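# Internal validation helpers. All user-facing errors are classed so tests can
# assert on condition class rather than message text.

stop_invalid <- function(field, msg) {
  abort(
    paste0("invalid `", field, "`: ", msg),
    class = c("glycoscreen_validation_error", "glycoscreen_error"),
    field = field
  )
}

stop_parse <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- paste0(msg, " (line ", line, ")")
  abort(msg, class = c("glycoscreen_parse_error", "glycoscreen_error"),
        line = line)
}

stop_analysis <- function(msg) {
  abort(msg, class = c("glycoscreen_analysis_error", "glycoscreen_error"))
}

stop_fit <- function(msg) {
  abort(msg, class = c("glycoscreen_fit_error", "glycoscreen_error"))
}

check_number <- function(x, field, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop_invalid(field, paste0("must be a finite numeric of length ", len))
  if (positive && any(x <= 0)) stop_invalid(field, "must be > 0")
  if (nonneg && any(x < 0)) stop_invalid(field, "must be >= 0")
  if (integerish && any(x != round(x)))
    stop_invalid(field, "must be a whole number")
  x
}

# Euclidean norms / angles on row-wise coordinate matrices
row_norm <- function(m) sqrt(rowSums(m * m))

# angle (degrees) at vertex b between points a and c; all n x 3 matrices
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- rowSums(u * v) / (row_norm(u) * row_norm(v))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

# unit vector(s) for n x 3 matrix
unit_rows <- function(m) m / row_norm(m)
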