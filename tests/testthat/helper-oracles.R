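# Independent brute-force oracles for the structural metrics, written
# directly from Burt's definitions on the full ego-included graph, with
# explicit loops.  They share no code with the package implementation.

# adjacency of the full graph: vertex 1 = ego (tied to all alters),
# vertices 2..n+1 = alters with the given tie matrix
full_adjacency <- function(ties) {
  n <- nrow(ties)
  A <- matrix(0, n + 1, n + 1)
  if (n > 0) {
    A[1, 2:(n + 1)] <- 1
    A[2:(n + 1), 1] <- 1
    A[2:(n + 1), 2:(n + 1)] <- ties * 1
  }
  A
}

# aggregate constraint of vertex i: C_i = sum_j (p_ij + sum_q p_iq p_qj)^2
# over j != i with a_ij > 0; p_uv = a_uv / sum_w a_uw
oracle_constraint <- function(ties, scale100 = TRUE) {
  n <- nrow(ties)
  if (n < 1) return(NA_real_)
  A <- full_adjacency(ties)
  m <- n + 1
  p <- matrix(0, m, m)
  for (u in 1:m) {
    du <- sum(A[u, ])
    if (du > 0) p[u, ] <- A[u, ] / du
  }
  i <- 1
  C <- 0
  for (j in 2:m) {
    if (A[i, j] == 0) next
    indirect <- 0
    for (q in 1:m) {
      if (q == i || q == j) next
      indirect <- indirect + p[i, q] * p[q, j]
    }
    C <- C + (p[i, j] + indirect)^2
  }
  if (scale100) 100 * C else C
}

# effective size of the ego: ES = sum_j (1 - sum_q p_iq m_jq), q != i,j;
# m_jq = a_jq / max_k a_jk (marginal tie strength of j on q)
oracle_effective_size <- function(ties) {
  n <- nrow(ties)
  if (n < 1) return(NA_real_)
  A <- full_adjacency(ties)
  m <- n + 1
  i <- 1
  ES <- 0
  for (j in 2:m) {
    redundancy <- 0
    maxj <- max(A[j, ])
    for (q in 2:m) {
      if (q == j) next
      p_iq <- A[i, q] / sum(A[i, ])
      m_jq <- if (maxj > 0) A[j, q] / maxj else 0
      redundancy <- redundancy + p_iq * m_jq
    }
    ES <- ES + (1 - redundancy)
  }
  ES
}

# all symmetric binary tie matrices over n alters
enumerate_tie_matrices <- function(n) {
  npairs <- n * (n - 1) / 2
  lapply(seq_len(2^npairs) - 1, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(max(npairs, 1))]
    m <- matrix(FALSE, n, n)
    if (npairs > 0) {
      m[upper.tri(m)] <- bits[seq_len(npairs)] == 1
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    m
  })
}

random_ego_network <- function(n, p_tie = 0.5, id = "p") {
  ego_network(id, alters = data.frame(alter_id = seq_len(n)),
              ties = tie_matrix(n, which_pairs(n, p_tie)))
}

which_pairs <- function(n, p_tie) {
  if (n < 2) return(list())
  pairs <- utils::combn(n, 2, simplify = FALSE)
  pairs[runif(length(pairs)) < p_tie]
}

# build a tiny cohort from explicit per-participant specs
toy_cohort <- function(specs, codebook = persnet_codebook()) {
  parts <- purrr::map_dfr(specs, function(s) {
    tibble::tibble(participant_id = s$id,
                   timepoint = s$timepoint %||% "pandemic",
                   group = s$group %||% "pwms",
                   !!!(s$fields %||% list()))
  })
  parts$network <- purrr::map(specs, function(s) {
    ego_network(s$id, s$timepoint %||% "pandemic", s$alters,
                s$ties %||% NULL)
  })
  persnet:::new_persnet_cohort(parts, codebook)
}
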