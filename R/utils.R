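# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap phase values to the principal interval
#'
#' Maps angles (radians) to (-pi, pi]. At the PRF sensitivity used here
#' (~0.075 rad/degC) a full wrap corresponds to ~83 degC of change, far above
#' the dynamic range of a phantom sonication, so no temporal unwrapping chain
#' is needed beyond this.
#'
#' @param x numeric vector/array of angles in radians.
#' @return same shape, wrapped to (-pi, pi].
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * round(x / (2 * pi))
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

# Shift a matrix by one cell with replicated (Neumann) edges.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Label 8-connected components of a logical matrix; returns an integer matrix
# (0 = background). Masks here are small, so a plain BFS is adequate.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      r <- ((v - 1L) %% nr) + 1L
      c <- ((v - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        w <- (cc - 1L) * nr + rr
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# Derive a reproducible child seed below 2^31 from a base seed and a counter.
derive_seed <- function(base_seed, counter) {
  as.integer((as.double(base_seed) * 7919 + as.double(counter) * 104729) %%
               2147483647)
}
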