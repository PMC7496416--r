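# Seeded generators for every input modality, each returning its dataset
# together with a GeneratorTruth list recording seed and planted ground
# truth, so downstream recovery can be checked analytically.

#' Generate a labeled alignment with planted group-specific bias
#'
#' Rest sequences draw every column independently from the background
#' distribution. Group sequences do the same except at planted columns,
#' where the column distribution is the mixture
#' \eqn{(1-\delta)\,q + \delta\,e_r} concentrating extra mass
#' \eqn{\delta} on the planted residue (so \eqn{\delta = 1} makes the
#' column monomorphic in the group and \eqn{\delta = 0} leaves the groups
#' exchangeable).
#'
#' @param nGroup,nRest sequences in the tagged group and the complement.
#' @param nColumns alignment width.
#' @param planted data.frame with columns \code{column}, \code{residue},
#'   \code{delta}; may be empty.
#' @param background 20-vector of background residue frequencies, or
#'   \code{"uniform"}.
#' @param seed integer RNG seed.
#' @param groupTag,restTag architecture tags to assign.
#' @return list: \code{alignment} (a
#'   \code{\linkS4class{LabeledAlignment}}) and \code{truth}
#' @export
genAlignment <- function(nGroup, nRest, nColumns,
                         planted = data.frame(column = integer(),
                                              residue = character(),
                                              delta = numeric()),
                         background = "uniform", seed = 1,
                         groupTag = "NIT-ANTAR", restTag = "other") {
  q <- if (identical(background, "uniform")) rep(1 / 20, 20L)
       else background / sum(background)
  stopifnot(length(q) == 20L, all(q > 0),
            all(planted$column >= 1L & planted$column <= nColumns),
            all(planted$delta >= 0 & planted$delta <= 1),
            all(planted$residue %in% AA20))
  rng <- .seededRNG(seed)
  drawBlock <- function(n, colDists) {
    m <- vapply(seq_len(nColumns), function(j)
      sample(AA20, n, replace = TRUE, prob = colDists[[j]]),
      character(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    apply(m, 1L, paste, collapse = "")
  }
  restDists <- rep(list(q), nColumns)
  groupDists <- restDists
  for (i in seq_len(nrow(planted))) {
    e <- numeric(20L)
    e[match(planted$residue[i], AA20)] <- 1
    groupDists[[planted$column[i]]] <-
      (1 - planted$delta[i]) * q + planted$delta[i] * e
  }
  groupSeqs <- drawBlock(nGroup, groupDists)
  restSeqs <- drawBlock(nRest, restDists)
  rng$restore()
  ids <- c(sprintf("grp%04d", seq_len(nGroup)),
           sprintf("rest%04d", seq_len(nRest)))
  seqs <- setNames(c(groupSeqs, restSeqs), ids)
  labels <- setNames(c(rep(groupTag, nGroup), rep(restTag, nRest)), ids)
  list(alignment = LabeledAlignment(seqs, labels),
       truth = list(modality = "alignment", seed = seed,
                    n_group = nGroup, n_rest = nRest,
                    n_columns = nColumns, planted = planted,
                    background = q, group_tag = groupTag))
}

#' Generate a synthetic anisotropy titration
#'
#' Draws a titration from the Hill model at a preset's (or explicitly
#' given) parameters: log-spaced concentrations, replicate wells,
#' mean-one lognormal multiplicative noise of CV \code{noise_cv} plus a
#' small additive well-noise floor (\code{addSd} anisotropy units) that
#' keeps zero-amplitude control curves realistically noisy.
#'
#' @param preset a binding preset name (see \code{\link{listPresets}}), or
#'   NULL to use \code{params}.
#' @param seed integer RNG seed.
#' @param nConc number of concentrations (log-spaced).
#' @param nRep replicate wells per concentration.
#' @param params explicit parameter list with the fields of a binding
#'   preset (kd, hill_n, bmax, x_min, x_max, x_unit, noise_cv).
#' @param addSd additive Gaussian noise SD (anisotropy units).
#' @return list: \code{curve} (a \code{\linkS4class{BindingCurve}}) and
#'   \code{truth}
#' @export
genBindingCurve <- function(preset = "P1P2-nitrate", seed = 1, nConc = 12,
                            nRep = 4, params = NULL, addSd = 0.002) {
  p <- if (is.null(params)) presetParams("binding", preset) else params
  rng <- .seededRNG(seed)
  x <- rep(.logSpaced(p$x_min, p$x_max, nConc), each = nRep)
  mu <- if (p$bmax > 0) hillModel(x, p$kd, p$hill_n, p$bmax) else rep(0, length(x))
  sdlog <- sqrt(log(1 + p$noise_cv^2))
  response <- mu * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog) +
    stats::rnorm(length(x), 0, addSd)
  rng$restore()
  curve <- bindingCurve(x, response,
                        replicate = rep(seq_len(nRep), times = nConc),
                        condition = if (is.null(params)) preset else "custom",
                        xUnit = p$x_unit)
  list(curve = curve,
       truth = list(modality = "binding", seed = seed,
                    preset = if (is.null(params)) preset else NA,
                    kd = p$kd, hill_n = p$hill_n, bmax = p$bmax,
                    noise_cv = p$noise_cv, add_sd = addSd,
                    n_conc = nConc, n_rep = nRep))
}

#' Generate synthetic gel lanes from a transcription preset
#'
#' @param preset a gel preset name, or NULL to use \code{trueFraction}.
#' @param seed integer RNG seed.
#' @param totalMolecules transcripts per lane.
#' @param noiseCv lognormal band-intensity noise CV.
#' @param nLanes replicate lanes.
#' @param trueFraction explicit readthrough fraction when no preset is
#'   used.
#' @return list: \code{lanes} (data.frame) and \code{truth}
#' @export
genGelLanes <- function(preset = "WT-plus-nitrate", seed = 1,
                        totalMolecules = 10000, noiseCv = 0.05,
                        nLanes = 1, trueFraction = NULL) {
  if (is.null(trueFraction)) {
    p <- presetParams("gel", preset)
    trueFraction <- p$fraction_ro
    uT <- p$u_count_T; uRO <- p$u_count_RO
    condition <- preset
  } else {
    uT <- uRO <- 25
    condition <- "custom"
  }
  lanes <- simulateLanes(trueFraction, totalMolecules = totalMolecules,
                         noiseCv = noiseCv, uCountT = uT, uCountRO = uRO,
                         nLanes = nLanes, condition = condition,
                         seed = seed)
  list(lanes = lanes,
       truth = list(modality = "gel", seed = seed, preset = condition,
                    true_fraction = trueFraction,
                    total_molecules = totalMolecules, noise_cv = noiseCv))
}

#' Generate a SELEX experiment from a pool preset
#'
#' @param preset a selex preset name.
#' @param seed integer RNG seed.
#' @param ... overrides passed on to \code{\link{simulateSelex}} (e.g.
#'   \code{poolSize}, \code{beta}).
#' @return list: \code{experiment} (a
#'   \code{\linkS4class{SelexExperiment}}) and \code{truth}
#' @export
genSelexPool <- function(preset = "tandem-hairpin-pool", seed = 1, ...) {
  p <- presetParams("selex", preset)
  args <- list(poolSize = p$pool_size, seqLen = p$seq_len,
               rounds = p$rounds, beta = p$beta, epsilon = p$epsilon,
               s0 = p$s0, seed = seed, plantedMotif = p$planted_motif,
               plantedFrequency = p$planted_frequency)
  override <- list(...)
  args[names(override)] <- override
  exp <- do.call(simulateSelex, args)
  list(experiment = exp,
       truth = c(list(modality = "selex", preset = preset), args))
}

# Minimal residue builders for toy structures: atoms are placed on a line
# from the backbone anchor so that the terminal functional atom sits at a
# requested point. Geometry is schematic; only interatomic distances
# matter for contact analysis.
.toyResidue <- function(chain, resno, resname, origin, tipOffset) {
  atomsFor <- list(
    ALA = c("N", "CA", "C", "O", "CB"),
    SER = c("N", "CA", "C", "O", "CB", "OG"),
    LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
    ASN = c("N", "CA", "C", "O", "CB", "CG", "ND2", "OD1"),
    GLY = c("N", "CA", "C", "O"),
    PHE = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1",
            "CE2", "CZ"))
  nm <- atomsFor[[resname]]
  if (is.null(nm)) stop("no toy template for residue ", resname)
  k <- length(nm)
  # chain of atoms stepped 1.5 A apart toward the tip; the last atom lands
  # exactly at origin + tipOffset
  dir <- tipOffset / sqrt(sum(tipOffset^2))
  steps <- seq(0, sqrt(sum(tipOffset^2)), length.out = k)
  xyz <- t(vapply(steps, function(s) origin + s * dir, numeric(3)))
  if (resname == "PHE") {
    # spread the six ring atoms on a hexagon around the tip so a ring
    # centroid exists
    ringIdx <- match(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"), nm)
    centre <- origin + tipOffset
    ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
    ring <- cbind(centre[1] + 1.4 * cos(ang), centre[2] + 1.4 * sin(ang),
                  centre[3])
    xyz[ringIdx, ] <- ring
  }
  data.frame(chain = chain, resno = resno, resname = resname, atom = nm,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a toy two-domain structure with planted contacts
#'
#' Builds a schematic coordinate set with two "helices" (chain A residues
#' 1..n and chain B residues 101..) whose residues are spaced far apart,
#' then plants the requested interdomain contacts by placing residue pairs
#' with their functional atoms at contact distance: \code{salt_bridge}
#' (Lys NZ 2.9 A from Glu OE1), \code{hbond} (Ser OG 2.9 A from Asn OD1),
#' \code{vdw} (Ala CB 3.6 A from Ala CB) and \code{aromatic} (two Phe
#' rings with centroids 4.5 A apart). Decoy residues sit at least 20 A
#' from everything else.
#'
#' @param planted character vector of contact types to plant, drawn from
#'   \code{"salt_bridge"}, \code{"hbond"}, \code{"vdw"},
#'   \code{"aromatic"}.
#' @param nDecoysPerDomain additional non-contacting residues per domain.
#' @param seed integer RNG seed (used only to jitter decoy placement).
#' @return list: \code{coords} (a \code{\linkS4class{CoordinateSet}}),
#'   \code{domainA}, \code{domainB} (\code{\linkS4class{DomainSpec}}) and
#'   \code{truth} listing the planted pairs with expected classes
#' @export
genToyStructure <- function(planted = c("salt_bridge", "hbond"),
                            nDecoysPerDomain = 3, seed = 1) {
  types <- planted
  known <- c("salt_bridge", "hbond", "vdw", "aromatic")
  if (length(bad <- setdiff(types, known)))
    stop("unknown contact type(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(known, collapse = ", "))
  rng <- .seededRNG(seed)
  recipes <- list(
    salt_bridge = list(resA = "LYS", resB = "GLU", gap = 2.9,
                       class = "salt_bridge_candidate"),
    hbond = list(resA = "SER", resB = "ASN", gap = 2.9,
                 class = "hbond_candidate"),
    vdw = list(resA = "ALA", resB = "ALA", gap = 3.6,
               class = "vdw_contact"),
    aromatic = list(resA = "PHE", resB = "PHE", gap = 4.5,
                    class = "aromatic_stack_candidate"))
  rows <- list()
  truthPairs <- list()
  resnoA <- 0L; resnoB <- 100L
  for (i in seq_along(types)) {
    rc <- recipes[[types[i]]]
    resnoA <- resnoA + 1L; resnoB <- resnoB + 1L
    base <- c(40 * i, 0, 0)  # planted pairs 40 A apart from each other
    tip <- base + c(0, 5, 0)  # shared contact point region
    # residue A grows upward to the tip; residue B grows downward from
    # gap A beyond the tip
    rows[[length(rows) + 1L]] <-
      .toyResidue("A", resnoA, rc$resA, base, c(0, 5, 0))
    rows[[length(rows) + 1L]] <-
      .toyResidue("B", resnoB, rc$resB, tip + c(0, rc$gap + 5, 0),
                  c(0, -5, 0))
    truthPairs[[length(truthPairs) + 1L]] <-
      data.frame(resno_a = resnoA, resno_b = resnoB,
                 type = types[i], expected_class = rc$class,
                 planted_distance = rc$gap, stringsAsFactors = FALSE)
  }
  for (j in seq_len(nDecoysPerDomain)) {
    resnoA <- resnoA + 1L; resnoB <- resnoB + 1L
    rows[[length(rows) + 1L]] <-
      .toyResidue("A", resnoA, "ALA",
                  c(-40 * j + stats::runif(1, -2, 2), -30, 0), c(0, 2, 0))
    rows[[length(rows) + 1L]] <-
      .toyResidue("B", resnoB, "ALA",
                  c(-40 * j + stats::runif(1, -2, 2), 60, 0), c(0, 2, 0))
  }
  rng$restore()
  coords <- CoordinateSet(do.call(rbind, rows))
  list(coords = coords,
       domainA = domainSpec("helixA", "A", cbind(1L, resnoA)),
       domainB = domainSpec("helixB", "B", cbind(101L, resnoB)),
       truth = list(modality = "structure", seed = seed,
                    planted = do.call(rbind, truthPairs)))
}

#' Generate a random toy structure for oracle cross-checks
#'
#' Residues with a few side-chain atoms scattered uniformly in a box, half
#' assigned to each of two chains; used to compare the contact scan
#' against an independent all-pairs oracle.
#'
#' @param nPerDomain residues per chain.
#' @param box box edge length, Angstrom.
#' @param seed integer RNG seed.
#' @return list: \code{coords}, \code{domainA}, \code{domainB}
#' @export
genRandomStructure <- function(nPerDomain = 10, box = 15, seed = 1) {
  rng <- .seededRNG(seed)
  resnames <- c("ALA", "SER", "LYS", "GLU", "ASN", "PHE", "GLY")
  build <- function(chain, offset) {
    do.call(rbind, lapply(seq_len(nPerDomain), function(i) {
      origin <- stats::runif(3, 0, box)
      tip <- stats::runif(3, -3, 3)
      if (all(tip == 0)) tip <- c(1, 0, 0)
      .toyResidue(chain, offset + i, sample(resnames, 1L), origin, tip)
    }))
  }
  at <- rbind(build("A", 0L), build("B", 100L))
  rng$restore()
  list(coords = CoordinateSet(at),
       domainA = domainSpec("A", "A", cbind(1L, nPerDomain)),
       domainB = domainSpec("B", "B", cbind(101L, 100L + nPerDomain)))
}
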