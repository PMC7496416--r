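# Interdomain residue contact detection and geometric classification.
# Classification is purely geometric (distance cutoffs on side-chain heavy
# atoms, donor/acceptor atoms and aromatic ring centroids); no energy model.

#' Define a domain selection
#'
#' @param name label for messages/output
#' @param chain chain identifier
#' @param ranges residue ranges in author numbering: either a string like
#'   \code{"328-397"} / \code{"1-100,150-200"} or an n x 2 matrix.
#' @return a \code{\linkS4class{DomainSpec}}
#' @export
domainSpec <- function(name, chain, ranges) {
  if (is.character(ranges)) {
    parts <- strsplit(strsplit(ranges, ",")[[1]], "-")
    ranges <- t(vapply(parts, function(p) as.integer(p[c(1L, length(p))]),
                       integer(2)))
  }
  ranges <- matrix(as.integer(ranges), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  new("DomainSpec", name = name, chain = chain, ranges = ranges)
}

.inDomain <- function(atoms, spec) {
  inRange <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(spec@ranges)))
    inRange <- inRange | (atoms$resno >= spec@ranges[i, 1] &
                          atoms$resno <= spec@ranges[i, 2])
  atoms$chain == spec@chain & inRange
}

# Side-chain heavy atoms of one residue's atom rows; glycine falls back to CA.
.sideChain <- function(res) {
  sc <- res[!(res$atom %in% BACKBONE_ATOMS) &
            !grepl("^H", res$atom), , drop = FALSE]
  if (nrow(sc) == 0L) sc <- res[res$atom == "CA", , drop = FALSE]
  sc
}

.minDist <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
        outer(a$z, b$z, "-")^2
  sqrt(min(d2))
}

.polarDist <- function(resA, resB) {
  pick <- function(res, tab) {
    atoms <- tab[[res$resname[1L]]]
    if (is.null(atoms)) res[0L, , drop = FALSE]
    else res[res$atom %in% atoms, , drop = FALSE]
  }
  min(.minDist(pick(resA, SIDECHAIN_DONORS), pick(resB, SIDECHAIN_ACCEPTORS)),
      .minDist(pick(resA, SIDECHAIN_ACCEPTORS), pick(resB, SIDECHAIN_DONORS)))
}

.ringCentroidDist <- function(resA, resB) {
  cen <- function(res) {
    ring <- AROMATIC_RING_ATOMS[[res$resname[1L]]]
    if (is.null(ring)) return(NULL)
    r <- res[res$atom %in% ring, , drop = FALSE]
    if (nrow(r) < 3L) return(NULL)
    c(mean(r$x), mean(r$y), mean(r$z))
  }
  ca <- cen(resA); cb <- cen(resB)
  if (is.null(ca) || is.null(cb)) return(Inf)
  sqrt(sum((ca - cb)^2))
}

.classifyPair <- function(resA, resB, polarDist, polarCutoff,
                          centroidCutoff) {
  na <- resA$resname[1L]; nb <- resB$resname[1L]
  opposite <- (na %in% POSITIVE_RESIDUES && nb %in% NEGATIVE_RESIDUES) ||
              (na %in% NEGATIVE_RESIDUES && nb %in% POSITIVE_RESIDUES)
  if (opposite && is.finite(polarDist) && polarDist <= polarCutoff)
    return("salt_bridge_candidate")
  if (is.finite(polarDist) && polarDist <= polarCutoff)
    return("hbond_candidate")
  if (na %in% names(AROMATIC_RING_ATOMS) &&
      nb %in% names(AROMATIC_RING_ATOMS) &&
      .ringCentroidDist(resA, resB) <= centroidCutoff)
    return("aromatic_stack_candidate")
  "vdw_contact"
}

#' Detect candidate residue pairing between two domains
#'
#' Scans all residue pairs with one residue in each domain and reports a
#' contact whenever the minimum side-chain heavy-atom distance is within
#' \code{heavyCutoff}. Each contact is classed geometrically:
#' \code{salt_bridge_candidate} (opposite formal side-chain charges with a
#' donor/acceptor pair within \code{polarCutoff}), \code{hbond_candidate}
#' (any side-chain donor-acceptor pair within \code{polarCutoff}),
#' \code{aromatic_stack_candidate} (both aromatic, ring centroids within
#' \code{centroidCutoff}), else \code{vdw_contact}. Results are sorted by
#' increasing heavy-atom distance.
#'
#' Note the salt-bridge test requires the polar-distance condition, so an
#' Arg/Glu pair touching only through CB atoms is reported as a van der
#' Waals contact, not a salt bridge.
#'
#' @param coords a \code{\linkS4class{CoordinateSet}}
#' @param a,b \code{\linkS4class{DomainSpec}} selections for the two domains
#' @param heavyCutoff side-chain heavy-atom distance cutoff, Angstrom
#' @param polarCutoff donor/acceptor distance cutoff, Angstrom
#' @param centroidCutoff aromatic ring-centroid cutoff, Angstrom
#' @return data.frame, one row per contact: chain/resno/resname for both
#'   sides, min_heavy_distance, min_polar_distance (NA when neither side
#'   offers a donor/acceptor pair), interaction_class
#' @export
interdomainContacts <- function(coords, a, b, heavyCutoff = 4.0,
                                polarCutoff = 3.5, centroidCutoff = 5.5) {
  at <- atoms(coords)
  selA <- at[.inDomain(at, a), , drop = FALSE]
  selB <- at[.inDomain(at, b), , drop = FALSE]
  if (nrow(selA) == 0L)
    stop("domain '", a@name, "' selects no atoms")
  if (nrow(selB) == 0L)
    stop("domain '", b@name, "' selects no atoms")
  resA <- split(selA, paste(selA$chain, selA$resno))
  resB <- split(selB, paste(selB$chain, selB$resno))
  rows <- list()
  for (ra in resA) {
    scA <- .sideChain(ra)
    for (rb in resB) {
      scB <- .sideChain(rb)
      d <- .minDist(scA, scB)
      if (d <= heavyCutoff) {
        pd <- .polarDist(ra, rb)
        rows[[length(rows) + 1L]] <- data.frame(
          chain_a = ra$chain[1L], resno_a = ra$resno[1L],
          resname_a = ra$resname[1L],
          chain_b = rb$chain[1L], resno_b = rb$resno[1L],
          resname_b = rb$resname[1L],
          min_heavy_distance = d,
          min_polar_distance = if (is.finite(pd)) pd else NA_real_,
          interaction_class = .classifyPair(ra, rb, pd, polarCutoff,
                                            centroidCutoff),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(chain_a = character(), resno_a = integer(),
                      resname_a = character(), chain_b = character(),
                      resno_b = integer(), resname_b = character(),
                      min_heavy_distance = numeric(),
                      min_polar_distance = numeric(),
                      interaction_class = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$min_heavy_distance, out$resno_a, out$resno_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate interface contacts with conservation evidence
#'
#' Joins each contact's two residues onto alignment-derived statistics
#' through a residue-number-to-column map: the differential KL divergence
#' of the mapped column, the compositional-bias delta of the residue's own
#' amino acid at that column, and (optionally) the conserved-position call.
#' Unmapped residues stay in the table with NA annotations; nothing is
#' dropped and input order is preserved.
#'
#' @param pairs contact table from \code{\link{interdomainContacts}}
#' @param columnMap named numeric vector: names are author residue numbers,
#'   values alignment columns (1-based).
#' @param scores optional \code{\linkS4class{PositionScores}} (metric
#'   \code{"dkl"}) for per-column divergence.
#' @param bias optional data.frame from \code{\link{compositionalBias}}.
#' @param calls optional data.frame from \code{\link{conservedPositions}}.
#' @return the contact table with added columns column_a/b, dkl_a/b,
#'   delta_a/b, call_a/b
#' @export
annotateContacts <- function(pairs, columnMap, scores = NULL, bias = NULL,
                             calls = NULL) {
  lookCol <- function(resno) {
    v <- columnMap[as.character(resno)]
    as.numeric(unname(v))
  }
  pairs$column_a <- lookCol(pairs$resno_a)
  pairs$column_b <- lookCol(pairs$resno_b)
  getDkl <- function(col) {
    if (is.null(scores)) return(rep(NA_real_, length(col)))
    tab <- scoreTable(scores)
    tab$bits[match(col, tab$column)]
  }
  pairs$dkl_a <- getDkl(pairs$column_a)
  pairs$dkl_b <- getDkl(pairs$column_b)
  one <- function(col, resname3) {
    if (is.null(bias)) return(NA_real_)
    aa <- .threeToOne(resname3)
    hit <- bias$delta[bias$column == col & bias$residue == aa]
    if (length(hit)) hit[1L] else NA_real_
  }
  pairs$delta_a <- mapply(function(col, rn)
    if (is.na(col)) NA_real_ else one(col, rn),
    pairs$column_a, pairs$resname_a)
  pairs$delta_b <- mapply(function(col, rn)
    if (is.na(col)) NA_real_ else one(col, rn),
    pairs$column_b, pairs$resname_b)
  getCall <- function(col) {
    if (is.null(calls)) return(rep(NA_character_, length(col)))
    calls$call[match(col, calls$column)]
  }
  pairs$call_a <- getCall(pairs$column_a)
  pairs$call_b <- getCall(pairs$column_b)
  pairs
}

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.threeToOne <- function(x) {
  out <- .AA3TO1[toupper(x)]
  out[is.na(out)] <- NA_character_
  unname(out)
}
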