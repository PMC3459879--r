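# Internal helpers shared across modules.

# 3N vectors are ordered (x1, y1, z1, x2, y2, z2, ...): row-major over the
# N x 3 coordinate matrix.
xyz_to_vec <- function(xyz) as.vector(t(xyz))

vec_to_xyz <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

vnorm <- function(v) sqrt(sum(v * v))

# expand residue indices to 3N vector element indices
idx3 <- function(i) as.vector(rbind(3L * i - 2L, 3L * i - 1L, 3L * i))

stop_lm <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "loopmodes_error")))
}

# residue correspondence keys: one string per residue
residue_keys <- function(chain, resno, insert = NULL) {
  if (is.null(insert)) insert <- rep("", length(chain))
  insert[is.na(insert)] <- ""
  paste(chain, resno, insert, sep = "|")
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# breadth-first connected components of a 0/1 adjacency matrix
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[i, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# non-standard-evaluation column names used in ggplot2 calls
utils::globalVariables(c("mode", "overlap", "cumulative", "window_start",
                         "value", "difference", "chain"))
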