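# Independent brute-force oracles used to cross-check the package's
# implementations on small inputs. These deliberately share no code with
# the package internals: plain loops and direct formula evaluation only.

# --- direct-count profile / divergence oracle -------------------------------

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracleProfiles <- function(seqs, alpha) {
  mat <- do.call(rbind, strsplit(unname(seqs), ""))
  nc <- ncol(mat)
  freqs <- matrix(0, nc, 20, dimnames = list(NULL, AA))
  gapf <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- mat[, j]
    counts <- sapply(AA, function(a) sum(col == a))
    neff <- sum(counts)
    gapf[j] <- sum(col == "-") / length(col)
    if (neff == 0 && alpha == 0) freqs[j, ] <- 1 / 20
    else freqs[j, ] <- (counts + alpha) / (neff + 20 * alpha)
  }
  list(freqs = freqs, gap_fraction = gapf)
}

oracleKL <- function(p, q) {
  s <- 0
  for (k in seq_along(p)) if (p[k] > 0) s <- s + p[k] * log2(p[k] / q[k])
  unname(s)
}

# --- exhaustive tandem-hairpin oracle ---------------------------------------

.pairsAllowed <- c("AU", "UA", "GC", "CG", "GU", "UG")

oracleHairpins <- function(seq, minStem = 3, maxStem = 7, loopLen = 6) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- list()
  for (L in minStem:maxStem) {
    span <- 2 * L + loopLen
    if (span > n) next
    for (i in 1:(n - span + 1)) {
      ok <- TRUE
      for (k in 1:L) {
        pr <- paste0(ch[i + k - 1], ch[i + span - k])
        if (!pr %in% .pairsAllowed) { ok <- FALSE; break }
      }
      if (!ok) next
      loop <- ch[(i + L):(i + L + loopLen - 1)]
      sc <- L +
        2 * (ch[i + L - 1] == "C" && ch[i + L + loopLen] == "G") +
        (loop[1] == "A") + (loop[4] == "G")
      out[[length(out) + 1]] <- list(start = i, end = i + span - 1,
                                     score = sc)
    }
  }
  out
}

# Best total score of two non-overlapping hairpins (spacer 0..maxSpacer),
# or NA when no legal tandem placement exists.
oracleTandemScore <- function(seq, minStem = 3, maxStem = 7, loopLen = 6,
                              maxSpacer = 10) {
  hp <- oracleHairpins(seq, minStem, maxStem, loopLen)
  best <- NA_real_
  for (a in hp) for (b in hp) {
    spacer <- b$start - a$end - 1
    if (spacer >= 0 && spacer <= maxSpacer) {
      tot <- a$score + b$score
      if (is.na(best) || tot > best) best <- tot
    }
  }
  best
}

# --- all-pairs contact oracle -----------------------------------------------

# Minimum side-chain heavy-atom distance for every cross-domain residue
# pair, by explicit loops; glycine falls back to CA.
oracleContacts <- function(atomTable, chainA, rangeA, chainB, rangeB,
                           cutoff = 4.0) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  sideRows <- function(df) {
    sc <- df[!(df$atom %in% backbone), , drop = FALSE]
    if (nrow(sc) == 0) sc <- df[df$atom == "CA", , drop = FALSE]
    sc
  }
  selA <- atomTable[atomTable$chain == chainA &
                    atomTable$resno >= rangeA[1] &
                    atomTable$resno <= rangeA[2], ]
  selB <- atomTable[atomTable$chain == chainB &
                    atomTable$resno >= rangeB[1] &
                    atomTable$resno <= rangeB[2], ]
  out <- NULL
  for (ra in unique(selA$resno)) {
    A <- sideRows(selA[selA$resno == ra, ])
    for (rb in unique(selB$resno)) {
      B <- sideRows(selB[selB$resno == rb, ])
      dmin <- Inf
      for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
        d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
        if (d < dmin) dmin <- d
      }
      if (dmin <= cutoff)
        out <- rbind(out, data.frame(resno_a = ra, resno_b = rb,
                                     dist = dmin))
    }
  }
  out
}

# --- misc fixtures ----------------------------------------------------------

randomDistribution <- function(k = 20) {
  v <- rgamma(k, shape = 0.5) + 1e-12
  v / sum(v)
}

randomRNA <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# A two-residue cross-domain PDB fixture: Lys on chain A with NZ at
# nzPos, Glu on chain B with OE1 at oe1Pos.
writeSaltBridgePDB <- function(path, gap = 2.9) {
  fmt <- function(serial, name, resn, chain, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, name, resn, chain, resno, x, y, z,
            substr(name, 1, 1))
  lines <- c(
    fmt(1, " N",  "LYS", "A", 1, 0, 0, 0),
    fmt(2, " CA", "LYS", "A", 1, 1.5, 0, 0),
    fmt(3, " C",  "LYS", "A", 1, 3.0, 0, 0),
    fmt(4, " O",  "LYS", "A", 1, 3.5, 1.0, 0),
    fmt(5, " CB", "LYS", "A", 1, 1.5, 1.5, 0),
    fmt(6, " NZ", "LYS", "A", 1, 1.5, 4.0, 0),
    fmt(7, " N",  "GLU", "B", 2, 0, 10, 0),
    fmt(8, " CA", "GLU", "B", 2, 1.5, 10, 0),
    fmt(9, " C",  "GLU", "B", 2, 3.0, 10, 0),
    fmt(10, " O",  "GLU", "B", 2, 3.5, 9.0, 0),
    fmt(11, " CB", "GLU", "B", 2, 1.5, 8.5, 0),
    fmt(12, " OE1", "GLU", "B", 2, 1.5, 4.0 + gap, 0),
    "END")
  writeLines(lines, path)
  path
}
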