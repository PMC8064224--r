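# Internal helpers shared across modules.

# Row/column index sets of block b (1..9, row-major from the top-left) on the
# cropped 510 x 510 grid.
block_bounds <- function(block) {
  block <- as.integer(block)
  if (length(block) != 1L || is.na(block) || block < 1L || block > 9L)
    stop("`block` must be a single integer in 1..9", call. = FALSE)
  br <- (block - 1L) %/% 3L
  bc <- (block - 1L) %% 3L
  list(rows = br * BLOCK_N + seq_len(BLOCK_N),
       cols = bc * BLOCK_N + seq_len(BLOCK_N))
}

# Same index sets expressed on the uncropped 512 x 512 grid (crop removes one
# row/column at each edge, so everything shifts by one).
block_bounds_full <- function(block) {
  b <- block_bounds(block)
  list(rows = b$rows + 1L, cols = b$cols + 1L)
}

# Blocks forming the nasal and temporal columns on a standardized
# (OD-convention, nasal = right) map.
NASAL_BLOCKS <- c(3L, 6L, 9L)
TEMPORAL_BLOCKS <- c(1L, 4L, 7L)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_keyed <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
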