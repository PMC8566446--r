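## Small shared helpers: rotations, seeds, distance-expression parsing.

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula. Used by morphology randomisation (twist/rotate/tilt)
#' and by the fixture generators.
#'
#' @param axis numeric length-3; need not be normalised (must be non-zero).
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix (determinant +1).
#' @export
rotation_about_axis <- function(axis, angle) {
  stopifnot(length(axis) == 3, is.finite(axis), is.finite(angle))
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation taking unit direction `a` onto unit direction `b`.
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  sth <- sqrt(sum(v^2))
  if (sth < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite vectors: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(a[2] * p[3] - a[3] * p[2],
            a[3] * p[1] - a[1] * p[3],
            a[1] * p[2] - a[2] * p[1])
    return(rotation_about_axis(ax, pi))
  }
  rotation_about_axis(v, atan2(sth, cth))
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

# Derive a reproducible child seed (< 2^31) from a master seed and a label.
# Plain 32-bit mixing so stage seeds decorrelate even for adjacent masters.
derive_seed <- function(seed, label) {
  h <- as.integer(seed %% 2147483647L)
  bytes <- utf8ToInt(as.character(label))
  for (b in c(bytes, 101L)) {
    h <- bitwXor(h, as.integer(b))
    h <- as.integer((as.double(h) * 31L + 7L) %% 2147483647L)
  }
  abs(h)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Parse a distance-dependent expression
#'
#' Pruning (`distPruning`) and input placement (`synapseDensity`) accept
#' either an R function of one argument or a text expression in the variable
#' `d`. In both cases `d` is the path distance to the soma in **micrometres**
#' (expressions are typically written against the printed figures, which use
#' um). Only arithmetic and a small set of math primitives are allowed.
#'
#' @param expr a function of `d`, or a character scalar such as
#'   `"1/(1+exp(-(d-100)/10))"`, or `NULL`.
#' @return a vectorised function taking distance in metres (internal unit),
#'   or `NULL` if `expr` is `NULL`.
#' @export
parse_distance_expression <- function(expr) {
  if (is.null(expr)) return(NULL)
  if (is.function(expr)) {
    f <- expr
    return(function(d_m) f(d_m / .unit_um))
  }
  stopifnot(is.character(expr), length(expr) == 1)
  allowed <- c("exp", "log", "sqrt", "abs", "pmin", "pmax", "min", "max",
               "ifelse", ">", "<", ">=", "<=", "==", "+", "-", "*", "/",
               "^", "(", "sin", "cos", "tanh")
  e <- str2lang(expr)
  check <- function(x) {
    if (is.call(x)) {
      fn <- as.character(x[[1]])
      if (!fn %in% allowed)
        stop("disallowed function in distance expression: ", fn)
      lapply(as.list(x)[-1], check)
    } else if (is.name(x)) {
      if (!identical(as.character(x), "d") && !identical(as.character(x), "pi"))
        stop("distance expressions may only use the variable 'd'")
    } else if (!is.numeric(x) && !is.logical(x)) {
      stop("invalid token in distance expression")
    }
    invisible(NULL)
  }
  check(e)
  function(d_m) {
    v <- eval(e, envir = list(d = d_m / .unit_um), enclos = baseenv())
    as.numeric(v) + numeric(length(d_m)) * 0  # recycle scalars
  }
}
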