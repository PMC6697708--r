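# Independent oracles used to cross-check the implementation.  These share
# no code with the package internals they test.

# --- quaternion (Horn) rigid superposition oracle -------------------------
# returns the proper rotation/translation mapping b onto a, plus rmsd
quat_superpose <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  S <- t(b0) %*% a0  # S[k, l] = sum_i b_k a_l
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), nrow = 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
  moved <- sweep(b0 %*% t(R), 2, ca, "+")
  list(rotation = R, translation = ca - as.vector(R %*% cb),
       rmsd = sqrt(mean(rowSums((a - moved)^2))))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# --- Gotoh affine-gap global alignment score oracle -----------------------
# gap of length L costs open + L * ext (the convention global_align documents)
gotoh_score <- function(a, b, submat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e12
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(n, letters = aa20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# --- direct per-column entropy oracle -------------------------------------
entropy_oracle <- function(col, base = 2) {
  col <- col[col %in% aa20]
  if (length(col) == 0) return(0)
  p <- as.vector(table(col)) / length(col)
  -sum(p * log(p)) / log(base)
}

# --- naive sliding-window motif oracle ------------------------------------
motif_oracle <- function(seq, pattern) {
  sv <- strsplit(seq, "")[[1]]; pv <- strsplit(pattern, "")[[1]]
  k <- length(pv)
  hits <- integer(0)
  for (i in seq_len(length(sv) - k + 1)) {
    win <- sv[i:(i + k - 1)]
    if (all(pv == "x" | pv == win)) hits <- c(hits, i)
  }
  hits
}

# rigidly transform every coordinate of a dh_structure
transform_structure <- function(s, R, t) {
  for (slot in c("atoms", "ligands")) {
    if (nrow(s[[slot]]) == 0) next
    xyz <- sweep(as.matrix(s[[slot]][, c("x", "y", "z")]) %*% t(R), 2, t, "+")
    s[[slot]]$x <- xyz[, 1]; s[[slot]]$y <- xyz[, 2]; s[[slot]]$z <- xyz[, 3]
  }
  s
}

# brute-force His x Asp minimum N-O distance enumeration
dyad_oracle <- function(s, chain = "A") {
  at <- s$atoms[s$atoms$chain == chain, ]
  his <- unique(at$resno[at$resname == "HIS"])
  asp <- unique(at$resno[at$resname == "ASP"])
  best <- NULL
  for (h in his) {
    hn <- at[at$resno == h & at$atom %in% c("ND1", "NE2"), c("x", "y", "z")]
    for (a in asp) {
      ao <- at[at$resno == a & at$atom %in% c("OD1", "OD2"), c("x", "y", "z")]
      if (nrow(hn) == 0 || nrow(ao) == 0) next
      for (i in seq_len(nrow(hn))) for (j in seq_len(nrow(ao))) {
        d <- sqrt(sum((as.numeric(hn[i, ]) - as.numeric(ao[j, ]))^2))
        if (is.null(best) || d < best$d) best <- list(his = h, asp = a, d = d)
      }
    }
  }
  best
}

# build a tiny hand-written PDB file; returns its path
write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, b = 20, altloc = " ", record = "ATOM") {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
          record, serial, name, altloc, resname, chain, resno, x, y, z, occ, b,
          substr(name, 1, 1))
}
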