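# Independent brute-force oracle: exhaustive enumeration of every individual
# event path over a handful of cycles, accumulating probability mass into
# per-cycle state occupancy. Mirrors the documented within-cycle convention
# (diagnosis before other-cause death for the healthy state; other-cause
# death, BC death, distant recurrence in that order for tunnels) but shares
# no code with the matrix engine.
enumerate_cohort_oracle <- function(inc, mort, stage_dist, q, rd, qd,
                                    n_cycles) {
  stages <- c("dcis", "stage1", "stage2", "stage3", "stage4")
  occ <- lapply(0:n_cycles, function(i) numeric(0))

  add <- function(k, key, p) {
    cur <- occ[[k + 1]]
    cur[key] <- (if (key %in% names(cur)) cur[key] else 0) + p
    occ[[k + 1]] <<- cur
  }

  recurse <- function(state, k, p) {
    if (p == 0) return()
    add(k, paste(state, collapse = ":"), p)
    if (k == n_cycles) return()
    m <- mort[k + 1]
    if (state[1] == "healthy") {
      pd <- inc[k + 1]
      for (s in seq_along(stages)) {
        recurse(c("tunnel", stages[s], 1), k + 1, p * pd * stage_dist[s])
      }
      recurse("dead_other", k + 1, p * (1 - pd) * m)
      recurse("healthy", k + 1, p * (1 - pd) * (1 - m))
    } else if (state[1] == "tunnel") {
      s <- match(state[2], stages); j <- as.integer(state[3])
      recurse("dead_other", k + 1, p * m)
      alive <- p * (1 - m)
      recurse("dead_bc", k + 1, alive * q[s, j])
      rem <- alive * (1 - q[s, j])
      recurse("distant", k + 1, rem * rd[s, j])
      stay <- rem * (1 - rd[s, j])
      if (j < 20) {
        recurse(c("tunnel", stages[s], j + 1), k + 1, stay)
      } else {
        recurse("survivor", k + 1, stay)
      }
    } else if (state[1] == "distant") {
      recurse("dead_other", k + 1, p * m)
      alive <- p * (1 - m)
      recurse("dead_bc", k + 1, alive * qd)
      recurse("distant", k + 1, alive * (1 - qd))
    } else if (state[1] == "survivor") {
      recurse("dead_other", k + 1, p * m)
      recurse("survivor", k + 1, p * (1 - m))
    } else {  # absorbing dead states
      recurse(state, k + 1, p)
    }
  }
  recurse("healthy", 0, 1)

  # translate to the engine's state labels
  out <- matrix(0, nrow = n_cycles + 1, ncol = 105,
                dimnames = list(cycle = 0:n_cycles, state = NULL))
  labels <- c("healthy",
              as.vector(outer(stages, 1:20,
                              function(s, y) paste0(s, "_y", y))),
              "distant_recurrence", "long_term_survivor", "dead_bc",
              "dead_other")
  colnames(out) <- labels
  for (k in 0:n_cycles) {
    cur <- occ[[k + 1]]
    for (key in names(cur)) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      lab <- switch(parts[1],
                    healthy = "healthy",
                    tunnel = paste0(parts[2], "_y", parts[3]),
                    distant = "distant_recurrence",
                    survivor = "long_term_survivor",
                    dead_bc = "dead_bc",
                    dead_other = "dead_other")
      out[k + 1, lab] <- out[k + 1, lab] + cur[key]
    }
  }
  out
}
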