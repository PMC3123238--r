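# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) stop("cannot normalise a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between two vectors, degrees, clamped against fp drift
vec_angle <- function(a, b) {
  ca <- sum(unitize(a) * unitize(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}

# residue key used throughout: "<resno>" or "<resno><insert>"
residue_key <- function(resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(resno, ins)
}
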