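#' Simulation configuration for synthetic multi-plex PSM tables
#'
#' Describes the forward model of the synthetic benchmark generator.
#' One plex is laid out by \code{composition}: per channel a role and,
#' for sample channels, a sample name and group, plus one amount column
#' per species giving the mixed protein amount of that species in that
#' channel (arbitrary mass units, e.g. micrograms).  The same layout is
#' replicated over \code{nPlexes} plexes, each with its own global
#' intensity scale factor (the batch effect).
#'
#' The forward model per PSM: protein abundance is lognormal per
#' species; the true channel intensity is abundance x species amount x
#' plex batch factor x a lognormal per-PSM ionization scale; with
#' contamination fraction f a background-proteome reporter pattern is
#' added at relative amount f/(1-f) and the record's PIF is set to 1-f;
#' impurity mixing \eqn{y = A^T x} is applied; finally each channel is
#' multiplied by lognormal noise.  Precursor intensity is the PSM's
#' summed true signal times lognormal noise; fill time is uniform.
#'
#' @param labelSet a [LabelSet-class] or preset name.
#' @param composition data.frame with columns \code{channel},
#'   \code{role}, \code{sample}, \code{group} plus one numeric amount
#'   column per species.
#' @param nPlexes number of plexes.
#' @param proteinsPerSpecies named integer vector: proteins simulated
#'   per species.
#' @param psmsPerProtein Poisson mean of PSMs per protein per plex.
#' @param abundanceSigma lognormal sigma (natural-log units) of protein
#'   base abundance; 2 is a standard proteome dynamic-range stand-in.
#' @param psmSigma lognormal sigma of the per-PSM ionization scale.
#' @param noiseSigma lognormal sigma of the per-channel reporter noise.
#' @param batchFactors positive per-plex intensity scale factors
#'   (default all 1 = no batch effect).
#' @param contaminationMax co-isolation contamination fractions are
#'   drawn uniformly on [0, contaminationMax]; 0 disables interference.
#' @param backgroundSpecies species whose mixing profile the co-isolated
#'   background follows (default: first species), which is what
#'   compresses foreground species ratios toward the background's.
#' @param correctionFactors optional [CorrectionFactors-class] to
#'   forward-apply as impurity leakage (NULL = identity).
#' @param precursorSigma lognormal sigma of the precursor intensity.
#' @param fillTimeRange uniform range (ms) of ion injection times.
#' @param name preset name carried along for provenance.
#' @return a validated configuration list of class \code{"SimConfig"}.
#' @seealso [simPreset()] for the shipped benchmark designs,
#'   [simulatePlexes()] to draw a data set.
#' @export
simConfig <- function(labelSet, composition, nPlexes = 1L,
                      proteinsPerSpecies, psmsPerProtein = 5,
                      abundanceSigma = 2, psmSigma = 1, noiseSigma = 0.1,
                      batchFactors = NULL, contaminationMax = 0,
                      backgroundSpecies = NULL, correctionFactors = NULL,
                      precursorSigma = 0.5, fillTimeRange = c(5, 100),
                      name = "custom") {
  labelSet <- .asLabelSet(labelSet)
  composition <- as.data.frame(composition)
  need <- c("channel", "role", "sample", "group")
  if (!all(need %in% names(composition)))
    stop("composition needs columns channel, role, sample, group")
  species <- setdiff(names(composition), need)
  if (!length(species)) stop("composition has no species amount column")
  for (s in species) {
    a <- composition[[s]]
    if (!is.numeric(a) || anyNA(a) || any(a < 0))
      stop("species amounts must be numeric and >= 0 ('", s, "')")
  }
  if (!setequal(composition$channel, channelNames(labelSet)))
    stop("composition must cover every channel of the label set")
  composition <- composition[match(channelNames(labelSet),
                                   composition$channel), , drop = FALSE]
  if (is.null(batchFactors)) batchFactors <- rep(1, nPlexes)
  stopifnot(length(batchFactors) == nPlexes, all(batchFactors > 0),
            nPlexes >= 1, psmsPerProtein > 0, abundanceSigma >= 0,
            psmSigma >= 0, noiseSigma >= 0, contaminationMax >= 0,
            contaminationMax < 1, precursorSigma >= 0,
            length(fillTimeRange) == 2L, all(fillTimeRange > 0))
  if (is.null(names(proteinsPerSpecies)) ||
      !setequal(names(proteinsPerSpecies), species))
    stop("proteinsPerSpecies must be named by the composition's species")
  if (is.null(backgroundSpecies)) backgroundSpecies <- species[1L]
  stopifnot(backgroundSpecies %in% species)
  if (!is.null(correctionFactors))
    stopifnot(is(correctionFactors, "CorrectionFactors"))
  structure(list(labelSet = labelSet, composition = composition,
                 species = species, nPlexes = as.integer(nPlexes),
                 proteinsPerSpecies = proteinsPerSpecies,
                 psmsPerProtein = psmsPerProtein,
                 abundanceSigma = abundanceSigma, psmSigma = psmSigma,
                 noiseSigma = noiseSigma, batchFactors = batchFactors,
                 contaminationMax = contaminationMax,
                 backgroundSpecies = backgroundSpecies,
                 correctionFactors = correctionFactors,
                 precursorSigma = precursorSigma,
                 fillTimeRange = fillTimeRange, name = name),
            class = "SimConfig")
}

# per-species amount matrix: species x channels, label-set order
.amountMatrix <- function(cfg) {
  A <- t(as.matrix(cfg$composition[cfg$species]))
  colnames(A) <- cfg$composition$channel
  A
}

#' Shipped benchmark simulation presets
#'
#' Pre-parameterized [simConfig()]s emulating published benchmark
#' designs:
#' \describe{
#'   \item{\code{ds1_carrier}}{TMTpro 16-plex single-cell carrier
#'     design: channel 126 carries a bulk proteome at
#'     \code{carrierRatio} (14/42/98/210/434) times the single-cell
#'     amount, channel 127C is left empty, the remaining 14 channels are
#'     single-cell samples with a 2:1:1 human:ecoli:yeast composition.
#'     Impurity leakage from the bundled synthetic TMTpro template is
#'     forward-applied, so the carrier inflates its neighbor channels
#'     until corrected.}
#'   \item{\code{ds3_two_proteome}}{TMT 11-plex two-proteome dilution
#'     series: constant 50 units of human proteome per sample with
#'     yeast spiked at 1/1.75/3/5.2/9 units (two replicates per plex),
#'     plus one reference channel carrying 50 human + 3.9 yeast.}
#'   \item{\code{ds5_phospho_ratios}}{TMTpro 16-plex co-isolation
#'     benchmark: constant human background (100 units) with yeast at
#'     0/6/9/12 units in triplicate, channel 126 left empty, and
#'     uniform co-isolation contamination so that PIF filtering can be
#'     studied.}
#' }
#'
#' @param preset one of \code{"ds1_carrier"}, \code{"ds3_two_proteome"},
#'   \code{"ds5_phospho_ratios"}.
#' @param nPlexes number of plexes (batches).
#' @param carrierRatio carrier-to-single-cell ratio (ds1).
#' @param batchFactors optional per-plex scale factors.
#' @param ... further arguments passed on to [simConfig()] to override
#'   preset defaults (e.g. \code{noiseSigma = 0}).
#' @return a \code{SimConfig}.
#' @export
simPreset <- function(preset = c("ds1_carrier", "ds3_two_proteome",
                                 "ds5_phospho_ratios"),
                      nPlexes = NULL, carrierRatio = 434,
                      batchFactors = NULL, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    ds1_carrier = {
      ls16 <- labelSet("TMTpro16")
      ch <- channelNames(ls16)
      role <- ifelse(ch == "126", "carrier",
                     ifelse(ch == "127C", "empty", "sample"))
      prof <- c(human = 0.5, ecoli = 0.25, yeast = 0.25)
      comp <- data.frame(channel = ch, role = role,
                         sample = ifelse(role == "sample",
                                         paste0("sc_", ch), NA),
                         group = ifelse(role == "sample", "single_cell",
                                        NA))
      for (s in names(prof))
        comp[[s]] <- ifelse(role == "sample", prof[[s]],
                            ifelse(role == "carrier",
                                   carrierRatio * prof[[s]], 0))
      tmpl <- system.file("extdata", "tmtpro16_impurities_synthetic.tsv",
                          package = "plexquant")
      list(labelSet = ls16, composition = comp,
           nPlexes = if (is.null(nPlexes)) 1L else nPlexes,
           proteinsPerSpecies = c(human = 150, ecoli = 75, yeast = 75),
           psmsPerProtein = 4, noiseSigma = 0.1,
           correctionFactors = readCorrectionTemplate(tmpl, ls16),
           name = "ds1_carrier")
    },
    ds3_two_proteome = {
      ls11 <- labelSet("TMT11")
      ch <- channelNames(ls11)
      yeast <- c(rep(c(1, 1.75, 3, 5.2, 9), each = 2), 3.9)
      role <- c(rep("sample", 10), "reference")
      grp <- c(rep(paste0("y", c(1, 1.75, 3, 5.2, 9)), each = 2), NA)
      comp <- data.frame(channel = ch, role = role,
                         sample = ifelse(role == "sample",
                                         paste0(grp, "_", ch), NA),
                         group = grp, human = 50, yeast = yeast)
      list(labelSet = ls11, composition = comp,
           nPlexes = if (is.null(nPlexes)) 3L else nPlexes,
           proteinsPerSpecies = c(human = 200, yeast = 200),
           psmsPerProtein = 5, noiseSigma = 0.1,
           name = "ds3_two_proteome")
    },
    ds5_phospho_ratios = {
      ls16 <- labelSet("TMTpro16")
      ch <- channelNames(ls16)
      yeastAmt <- c(0, rep(c(0, 6, 9, 12), each = 3), rep(0, 3))
      role <- c("empty", rep("sample", 12), rep("empty", 3))
      grp <- c(NA, rep(paste0("y", c(0, 6, 9, 12)), each = 3),
               rep(NA, 3))
      comp <- data.frame(channel = ch, role = role,
                         sample = ifelse(role == "sample",
                                         paste0(grp, "_", ch), NA),
                         group = grp,
                         human = ifelse(role == "sample", 100, 0),
                         yeast = ifelse(role == "sample", yeastAmt, 0))
      list(labelSet = ls16, composition = comp,
           nPlexes = if (is.null(nPlexes)) 1L else nPlexes,
           proteinsPerSpecies = c(human = 300, yeast = 300),
           psmsPerProtein = 8, noiseSigma = 0.05,
           contaminationMax = 0.6, backgroundSpecies = "human",
           name = "ds5_phospho_ratios")
    })
  override <- list(...)
  if (!is.null(batchFactors)) override$batchFactors <- batchFactors
  args[names(override)] <- override
  do.call(simConfig, args)
}

#' Simulate a synthetic multi-plex PSM data set
#'
#' Draws a PSM table, its experimental design, and the full ground truth
#' from the forward model described in [simConfig()].  The same config
#' and seed always yield the identical table.
#'
#' @param cfg a [simConfig()] / [simPreset()] configuration.
#' @param seed integer RNG seed.
#' @return list with elements \code{psm} (PSM data.frame in the MaxQuant
#'   column dialect), \code{design} ([ExperimentalDesign-class]),
#'   \code{truth} (list: \code{proteins} with species and base
#'   abundance; \code{ratios} with the true sample/reference mixing
#'   ratio per sample and species for both normalization modes;
#'   \code{psm} with per-PSM protein, plex and true PIF; \code{trueX},
#'   the pre-leakage true reporter matrix) and \code{mixing} (the
#'   applied [MixingMatrix-class]).
#' @export
simulatePlexes <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(as.integer(seed))
  ls <- cfg$labelSet
  n <- nChannels(ls)
  comp <- cfg$composition
  amt <- .amountMatrix(cfg)                       # species x channels
  M <- if (is.null(cfg$correctionFactors))
    buildMixingMatrix(ls, correctionFactors(ls)) else
    buildMixingMatrix(ls, cfg$correctionFactors)
  A <- mixingMatrix(M)
  bg <- amt[cfg$backgroundSpecies, ]
  if (sum(bg) <= 0) stop("background species has zero total amount")
  bg <- bg / sum(bg)

  # design: composition replicated per plex, sample names suffixed
  destab <- do.call(rbind, lapply(seq_len(cfg$nPlexes), function(k) {
    d <- comp[c("channel", "role", "sample", "group")]
    d$plex <- paste0("plex", k)
    d$sample <- ifelse(is.na(d$sample), NA,
                       paste0(d$sample, "_p", k))
    d[c("plex", "channel", "role", "sample", "group")]
  }))
  design <- experimentalDesign(ls, destab)

  # protein ground truth
  prots <- do.call(rbind, lapply(cfg$species, function(s) {
    np <- cfg$proteinsPerSpecies[[s]]
    data.frame(protein = sprintf("%s_%03d", s, seq_len(np)), species = s,
               abundance = exp(rnorm(np, 0, cfg$abundanceSigma)))
  }))

  psmList <- list()
  truthList <- list()
  xList <- list()
  psmCounter <- 0L
  for (k in seq_len(cfg$nPlexes)) {
    for (s in cfg$species) {
      ps <- prots[prots$species == s, , drop = FALSE]
      npsm <- rpois(nrow(ps), cfg$psmsPerProtein)
      N <- sum(npsm)
      if (N == 0L) next
      pidx <- rep(seq_len(nrow(ps)), npsm)
      scale <- ps$abundance[pidx] *
        exp(rnorm(N, 0, cfg$psmSigma)) * cfg$batchFactors[k]
      X <- scale %o% amt[s, ]
      f <- if (cfg$contaminationMax > 0)
        runif(N, 0, cfg$contaminationMax) else rep(0, N)
      if (any(f > 0))
        X <- X + (f / (1 - f) * rowSums(X)) %o% bg
      Y <- X %*% A
      if (cfg$noiseSigma > 0)
        Y <- Y * exp(matrix(rnorm(N * n, 0, cfg$noiseSigma), N, n))
      precursor <- rowSums(X) * exp(rnorm(N, 0, cfg$precursorSigma))
      fill <- runif(N, cfg$fillTimeRange[1], cfg$fillTimeRange[2])
      ids <- sprintf("psm%06d", psmCounter + seq_len(N))
      psmCounter <- psmCounter + N
      tab <- data.frame(id = ids, check.names = FALSE)
      tab[.reporterCols(n)] <- as.data.frame(Y)
      tab[["Precursor intensity"]] <- precursor
      tab[["Ion injection time"]] <- fill
      tab[["PIF"]] <- 1 - f
      tab[["Base peak ratio"]] <- NA_real_
      tab[["Proteins"]] <- ps$protein[pidx]
      tab[["Experiment"]] <- paste0("plex", k)
      tab[["Plex"]] <- paste0("plex", k)
      psmList[[length(psmList) + 1L]] <- tab
      truthList[[length(truthList) + 1L]] <-
        data.frame(id = ids, protein = ps$protein[pidx],
                   plex = paste0("plex", k), species = s, pif = 1 - f)
      xList[[length(xList) + 1L]] <- X
    }
  }
  psm <- do.call(rbind, psmList)
  rownames(psm) <- NULL
  trueX <- do.call(rbind, xList)
  dimnames(trueX) <- list(psm$id, channelNames(ls))

  # configured mixing ratios per sample and species (plex-independent:
  # batch factors cancel inside a plex)
  si <- sampleInfo(design)
  ratios <- do.call(rbind, lapply(cfg$species, function(s) {
    refIdx <- which(comp$role == "reference")
    samIdx <- which(comp$role == "sample")
    refSum <- sum(amt[s, refIdx])
    allSum <- sum(amt[s, samIdx])
    ci <- match(si$channel, comp$channel)
    data.frame(sample = rownames(si), plex = si$plex, species = s,
               amount = amt[s, ci],
               ratioReference = if (length(refIdx)) amt[s, ci] / refSum
                                else NA_real_,
               ratioAllSum = amt[s, ci] / allSum)
  }))
  rownames(ratios) <- NULL

  list(psm = psm, design = design,
       truth = list(proteins = prots, ratios = ratios,
                    psm = do.call(rbind, truthList), trueX = trueX),
       mixing = M, config = cfg, seed = as.integer(seed))
}

#' Expected observed intensities under the forward model
#'
#' The closed-form expectation of every observed reporter intensity
#' with the channel noise conceptually set to zero: the true pre-leakage
#' reporter matrix (which already includes the co-isolation term) pushed
#' through the impurity mixing, \eqn{E[Y] = X A}.  Used as the oracle in
#' recovery tests.
#'
#' @param sim result of [simulatePlexes()].
#' @return numeric PSMs x channels matrix.
#' @export
expectedObserved <- function(sim) {
  sim$truth$trueX %*% mixingMatrix(sim$mixing)
}

#' Write a simulated data set to a directory
#'
#' Writes \code{psm.tsv} (MaxQuant-dialect PSM table),
#' \code{design.tsv}, \code{ground_truth.tsv} (per-sample true mixing
#' ratios per species) and \code{ground_truth_proteins.tsv} (per-protein
#' species and base abundance).
#'
#' @param sim result of [simulatePlexes()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePSMTable(sim$psm, file.path(dir, "psm.tsv"))
  writeDesign(sim$design, file.path(dir, "design.tsv"))
  .writeTsv(sim$truth$ratios, file.path(dir, "ground_truth.tsv"))
  .writeTsv(sim$truth$proteins,
            file.path(dir, "ground_truth_proteins.tsv"))
  invisible(dir)
}
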