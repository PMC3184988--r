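# Shared fixture builders for the test suite. Everything is generated in
# code; no files are read from disk.

# One fixed-column PDB coordinate line.
pdb_line <- function(serial, name, alt, res, chain, seq, x, y, z,
                     occ = 1.0, elem = "C", record = "ATOM", icode = " ") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else
    formatC(paste0(" ", name), width = -4)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, res, chain, seq, icode,
          x, y, z, occ, 0, formatC(elem, width = 2))
}

# Three-atom glycine in a single chain.
glycine_pdb <- function() {
  c(pdb_line(1, "N", " ", "GLY", "A", 1, 0, 0, 0, elem = "N"),
    pdb_line(2, "CA", " ", "GLY", "A", 1, 1.45, 0, 0),
    pdb_line(3, "C", " ", "GLY", "A", 1, 2.2, 1.2, 0),
    "END")
}

# A 16-residue helical chain with full pseudo-backbone plus an iron placed
# close to residue `near` so a handful of residues are heme-binding.
helix_heme_complex <- function(near = 8, dist_scale = 2.2) {
  s <- make_chain(16, "helix", full_backbone = TRUE)
  res <- protein_residues(s, "A")
  at <- res[[near]]$atoms
  ca <- c(at$x[at$name == "CA"], at$y[at$name == "CA"], at$z[at$name == "CA"])
  r <- sqrt(ca[1]^2 + ca[2]^2)
  lig <- data.frame(x = ca[1] / r * (r + 4.0), y = ca[2] / r * (r + 4.0),
                    z = ca[3], name = "FE", element = "FE")
  list(holo = make_complex(s, list(lig)), apo = s)
}

# Random small structure whose contact graph we can brute-force in tests.
cloud_structure <- function(n = 10, seed = 7) {
  make_chain(n, "cloud", radius = 6, min_sep = 2.5, seed = seed)
}

# Independent all-pairs minimum heavy-atom distance check (test-local
# oracle: no shared code with build_network).
brute_force_adjacency <- function(residues, cutoff) {
  n <- length(residues)
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ai <- residues[[i]]$atoms
    ai <- ai[ai$is_heavy, ]
    for (j in seq_len(n)) {
      if (i == j) next
      aj <- residues[[j]]$atoms
      aj <- aj[aj$is_heavy, ]
      dmin <- Inf
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          d <- sqrt(sum((c(ai$x[p], ai$y[p], ai$z[p]) -
                           c(aj$x[q], aj$y[q], aj$z[q]))^2))
          dmin <- min(dmin, d)
        }
      }
      A[i, j] <- as.integer(dmin < cutoff)
    }
  }
  A
}

# Wrap an adjacency matrix as a network object without using the builder.
graph_from_adjacency <- function(A) {
  ids <- paste0("R", seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  nodes <- data.frame(id = ids, chain_id = "A", seq_num = seq_len(nrow(A)),
                      icode = "", res_name = "GLY", res_type = "GLY",
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, adjacency = A), class = "hemenet_rin")
}

# All labeled simple graphs on n nodes (n small).
all_graphs <- function(n) {
  m <- n * (n - 1) / 2
  up <- which(upper.tri(matrix(0, n, n)))
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0L, n, n)
    A[up] <- bits
    A + t(A)
  })
}
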