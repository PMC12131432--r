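# Internal helpers: classed conditions, seeded evaluation, image validation.

artix_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "artix_error")))
}

artix_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "artix_warning")))
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. All generator functions funnel their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a master seed and a stream index, staying within
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647L)
}

assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    artix_error("artix_bad_image",
                sprintf("`%s` must be an H x W x 3 array of intensities", arg))
  }
  invisible(image)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) {
    artix_error("artix_bad_mask", sprintf("`%s` must be an H x W matrix", arg))
  }
  invisible(mask)
}

as_binary_mask <- function(mask) {
  assert_mask(mask)
  m <- mask > 0.5
  storage.mode(m) <- "logical"
  m
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
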