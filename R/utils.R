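# Internal helpers shared across modules.

expit <- function(x) plogis(x)
logit <- function(p) qlogis(p)

#' Derive a reproducible sub-seed from a top-level seed and a tag
#'
#' All randomness in the package is routed through a single top-level seed;
#' stage- or patient-level streams are spawned deterministically so that
#' adding or reordering stages never silently changes unrelated draws.
#' The result is always in `[1, 2^31 - 2]` (a valid 32-bit R seed).
#'
#' @param seed integer top-level seed.
#' @param ... further tags (coerced to character) identifying the substream.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h %% 2147483645L + 1L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_chacomed <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "chacomed_error"))
}

assert_that <- function(cond, ..., class = "chacomed_invalid") {
  if (!isTRUE(cond)) stop_chacomed(..., class = class)
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# linear index into a 3D array for an n x 3 integer voxel matrix
voxel_linear <- function(vox, dim) {
  (vox[, 1L]) + (vox[, 2L] - 1L) * dim[1L] + (vox[, 3L] - 1L) * dim[1L] * dim[2L]
}
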