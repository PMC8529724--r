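## Seeded generators for every input the pipeline consumes, each with a
## machine-readable truth table. Defaults are the study's stated world:
## 14 PDX models, 9 with a matched PD3D culture, 10 drugs; doubling
## times lognormal with mean 10.9 d and SD 6.2 d; treatment starts at
## palpable tumors (100 mm^3); twice-weekly caliper days over 3 weeks;
## 8 animals per arm; multiplicative lognormal caliper noise sigma 0.1;
## viability plates with 8 log-spaced doses, 4 replicates, Gaussian
## sigma 0.05; combination plates with n = 2 replicates.

#' Configuration for the synthetic study generators
#'
#' Returns the default stated-world configuration; any element can be
#' overridden via `...` (matched by name, recursively for the stage
#' sublists).
#'
#' @param seed root seed; each stage derives its own stream from it.
#' @param ... named overrides, e.g. `growth = list(sigma = 0)`.
#' @return nested named list understood by the `gen*()` generators.
#' @export
syntheticConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    nModels = 14L,
    nMatched = 9L,
    drugs = sprintf("drug%02d", 1:10),
    response = list(
      platformSD = 0.3                   # cross-platform latent jitter
    ),
    growth = list(
      baselineTV = 100,                  # mm^3, palpable start
      tdMean = 10.9, tdSD = 6.2,         # d, lognormal across models
      tdRange = c(4.2, 28.4),            # observed range, clamped
      tcRange = c(2, 120),               # target T/C span, percent
      sigma = 0.1,                       # lognormal caliper noise
      nAnimals = 8L,
      days = seq(0, 21, by = 3)
    ),
    doseResponse = list(
      doses = 10^seq(-3, 0.5, length.out = 8),   # uM
      topRange = c(0.95, 1.05),
      hillRange = c(0.8, 2.5),
      viabilityRange = c(2, 98),         # target Cmax viability, percent
      sigma = 0.05,
      nReplicates = 4L,
      resistantBottom = 0.9              # planted resistant model/drug
    ),
    expression = list(
      nGenes = 1000L,
      nMarkers = 50L,
      effectD = 2,                       # log2 shift in responders
      sharedVariance = 0.8,              # matched-triplet latent fraction
      noiseSD = 1,                       # per-platform log2 noise
      baselineRange = c(3, 8),           # log2 abundance means
      nSets = 10L,
      setSize = 30L
    ),
    combination = list(
      dosesA = c(0, 0.25, 0.5, 1, 2, 4),
      dosesB = c(0, 0.25, 0.5, 1, 2, 4),
      emax = 0.6, ec50 = 1, hill = 1.5,  # moderate effects: no clamping
      baselineEffect = 0.02,
      beta = 0.2,                        # Bliss interaction
      sigma = 0.02,
      nReplicates = 2L,
      confluence = 100
    )
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

## Latent drug sensitivity per (model, drug), shared by both platforms.
## 0 = strongest response, 1 = fully resistant. Seeded independently of
## the stage streams so every generator sees the same latents.
.responseLatents <- function(config) {
  set.seed(config$seed + 77L)
  matrix(stats::runif(config$nModels * length(config$drugs)),
         config$nModels, length(config$drugs),
         dimnames = list(sprintf("PDX%02d", seq_len(config$nModels)),
                         config$drugs))
}

## lognormal meanlog/sdlog matching a target mean and SD
.lnormPars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

## multiplicative noise with unit expectation
.unitLnorm <- function(n, sigma) {
  if (sigma == 0) rep(1, n) else stats::rlnorm(n, -sigma^2 / 2, sigma)
}

#' Generate caliper growth curves with known doubling times and T/C
#'
#' Tumor volumes follow TV(t) = TV0 x 2^(m t / td) x noise, where the
#' growth-rate multiplier m is 1 in control arms and the drug's effect
#' in treated arms (m < 0 shrinks the tumor). The effect is chosen so
#' that the analytic final-day T/C equals the target implied by the
#' (model, drug) latent sensitivity, log-spaced over
#' `growth$tcRange`; the same latent later drives the matched PD3D
#' viability, which is what makes matched platforms concordant. Width
#' and length are back-computed from TV = 0.5 w^2 l with an
#' aspect-ratio draw in [1.2, 2]. The truth table records each
#' model's doubling time, the effect multiplier and the analytic T/C
#' expectation 100 x 2^((m - 1) t / td) at the final day.
#'
#' @param config from [syntheticConfig()].
#' @return list: `records` (growth-schema `data.frame` including
#'   per-drug control arms), `truth` (`data.frame`: model, drug, td,
#'   effect, expected_tc, eval_day).
#' @export
genGrowth <- function(config = syntheticConfig()) {
  g <- config$growth
  u <- .responseLatents(config)
  set.seed(config$seed + 101L)
  models <- sprintf("PDX%02d", seq_len(config$nModels))
  lp <- .lnormPars(g$tdMean, g$tdSD)
  td <- stats::rlnorm(config$nModels, lp["meanlog"], lp["sdlog"])
  td <- pmin(pmax(td, g$tdRange[1]), g$tdRange[2])
  names(td) <- models
  tEval <- max(g$days)
  # latent -> target T/C (log scale) -> growth-rate multiplier
  tcTarget <- g$tcRange[1] * (g$tcRange[2] / g$tcRange[1])^u
  effects <- 1 + (td[rownames(u)] / tEval) * log2(tcTarget / 100)
  dimnames(effects) <- dimnames(u)
  rows <- list(); truth <- list()
  for (m in models) {
    arms <- c(stats::setNames(rep(1, 1), "control"),
              stats::setNames(effects[m, ], config$drugs))
    for (a in names(arms)) {
      mult <- arms[[a]]
      for (an in seq_len(g$nAnimals)) {
        tv <- g$baselineTV * 2^(mult * g$days / td[m]) *
          .unitLnorm(length(g$days), g$sigma)
        aspect <- stats::runif(length(g$days), 1.2, 2)
        w <- (2 * tv / aspect)^(1 / 3)
        rows[[length(rows) + 1L]] <- data.frame(
          model = m,
          drug = if (a == "control") "vehicle" else a,
          arm = if (a == "control") "control" else "treated",
          animal = sprintf("%s_%s_a%d", m, a, an),
          day = g$days, width_mm = w, length_mm = aspect * w)
      }
    }
    for (d in config$drugs)
      truth[[paste(m, d)]] <- data.frame(
        model = m, drug = d, td = unname(td[m]),
        effect = effects[m, d],
        expected_tc = 100 * 2^((effects[m, d] - 1) * tEval / td[m]),
        eval_day = tEval)
  }
  list(records = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate viability plates from known 4PL curves
#'
#' Each matched model x drug pair receives a 4PL curve whose viability
#' at Cmax hits the target implied by the shared (model, drug) latent
#' sensitivity plus cross-platform jitter (`response$platformSD` on
#' the latent scale): top and hill are drawn from the configured
#' ranges, bottom sits below the target, and the IC50 is solved from
#' the 4PL so the curve passes through the target at Cmax (then
#' clamped to the tested dose range). The first model is planted
#' resistant to the first drug (bottom raised to `resistantBottom`).
#' Cmax per drug is the 6th dose of the grid. The truth table records
#' the generating parameters and the noise-free viability at Cmax.
#'
#' @param config from [syntheticConfig()].
#' @param models character vector of model IDs; defaults to the
#'   matched PD3D cohort (matched to PDX models 1..nMatched by
#'   position).
#' @return list: `records` (viability schema), `cmax` (`data.frame`:
#'   drug, cmax_uM), `truth` (model, drug, top, bottom, ic50, hill,
#'   viability_at_cmax as a fraction).
#' @export
genViability <- function(config = syntheticConfig(),
                         models = sprintf("PD3D%02d",
                                          seq_len(config$nMatched))) {
  dr <- config$doseResponse
  u <- .responseLatents(config)
  set.seed(config$seed + 202L)
  doses <- dr$doses
  cmax <- stats::setNames(rep(doses[6], length(config$drugs)), config$drugs)
  rows <- list(); truth <- list()
  for (m in models) for (d in config$drugs) {
    iModel <- match(m, models)
    uPlat <- min(max(u[iModel, d] +
                     stats::rnorm(1, 0, config$response$platformSD),
                     0.005), 0.995)
    vTarget <- (dr$viabilityRange[1] +
                diff(dr$viabilityRange) * uPlat) / 100
    top <- stats::runif(1, dr$topRange[1], dr$topRange[2])
    hill <- stats::runif(1, dr$hillRange[1], dr$hillRange[2])
    vTarget <- min(vTarget, top - 0.02)
    bottom <- max(0, vTarget - stats::runif(1, 0.1, 0.4))
    # solve (cmax/ic50)^hill = (top - v)/(v - bottom) for ic50
    ratio <- (top - vTarget) / (vTarget - bottom)
    ic50 <- cmax[[d]] / ratio^(1 / hill)
    ic50 <- min(max(ic50, doses[1]), doses[length(doses)])
    if (m == models[1] && d == config$drugs[1]) {
      bottom <- dr$resistantBottom
      top <- max(top, bottom + 0.08)
      ic50 <- exp(mean(log(range(doses))))
    }
    mu <- .fourPL(rep(doses, each = dr$nReplicates), top, bottom, ic50, hill)
    v <- pmax(mu + stats::rnorm(length(mu), 0, dr$sigma), 0)
    rows[[paste(m, d)]] <- data.frame(
      model = m, drug = d,
      concentration_uM = rep(doses, each = dr$nReplicates),
      replicate = rep(seq_len(dr$nReplicates), times = length(doses)),
      viability = v)
    truth[[paste(m, d)]] <- data.frame(
      model = m, drug = d, top = top, bottom = bottom, ic50 = ic50,
      hill = hill, cmax = unname(cmax[d]),
      viability_at_cmax = .fourPL(cmax[[d]], top, bottom, ic50, hill))
  }
  list(records = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       cmax = data.frame(drug = config$drugs, cmax_uM = unname(cmax)),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate matched expression matrices with planted markers and sets
#'
#' Each matched model owns a latent log2 profile; its patient, PDX and
#' PD3D samples mix that profile with platform noise so that the
#' latent fraction of variance equals `sharedVariance`. The first
#' `nMarkers` genes are shifted up by `effectD` log2 units in all
#' samples of responder models. The first gene set is the planted
#' (enriched) set, built from marker genes; the remaining sets are
#' random draws from non-marker genes.
#'
#' @param config from [syntheticConfig()].
#' @return list: `matrices` (named list patient/PDX/PD3D of linear-
#'   scale gene x sample matrices), `labels` (named character:
#'   responder/resistant per model), `collection`
#'   ([GeneSetCollection]; set 1 planted), `truth` (list: markers,
#'   responders, effectD, sharedVariance).
#' @export
genExpression <- function(config = syntheticConfig()) {
  ex <- config$expression
  set.seed(config$seed + 303L)
  nG <- ex$nGenes
  genes <- sprintf("G%04d", seq_len(nG))
  models <- sprintf("M%02d", seq_len(config$nMatched))
  markers <- genes[seq_len(ex$nMarkers)]
  responders <- stats::setNames(
    sample(c("responder", "resistant"), config$nMatched, replace = TRUE),
    models)
  # guarantee at least two models per class (contrasts need n >= 2)
  want <- min(2L, config$nMatched %/% 2L)
  for (cl in c("responder", "resistant")) {
    short <- want - sum(responders == cl)
    if (short > 0) {
      other <- which(responders != cl)
      responders[other[seq_len(short)]] <- cl
    }
  }
  base <- stats::runif(nG, ex$baselineRange[1], ex$baselineRange[2])
  rho <- ex$sharedVariance
  platforms <- c("patient", "PDX", "PD3D")
  mats <- lapply(platforms, function(p)
    matrix(0, nG, config$nMatched,
           dimnames = list(genes, paste(models, p, sep = "_"))))
  names(mats) <- platforms
  for (i in seq_along(models)) {
    latent <- stats::rnorm(nG, 0, ex$noiseSD)
    shift <- if (responders[i] == "responder")
      ifelse(genes %in% markers, ex$effectD, 0) else 0
    for (p in platforms) {
      eps <- stats::rnorm(nG, 0, ex$noiseSD)
      l2 <- base + shift + sqrt(rho) * latent + sqrt(1 - rho) * eps
      mats[[p]][, i] <- 2^l2
    }
  }
  nonMarkers <- setdiff(genes, markers)
  sets <- vector("list", ex$nSets)
  sets[[1]] <- sample(markers, min(ex$setSize, length(markers)))
  for (s in seq_len(ex$nSets)[-1])
    sets[[s]] <- sample(nonMarkers, ex$setSize)
  collection <- new("GeneSetCollection",
    setNames = c("planted_response",
                 sprintf("null_set%02d", seq_len(ex$nSets)[-1])),
    descriptions = c("planted responder-associated set",
                     rep("random null set", ex$nSets - 1L)),
    genes = sets)
  list(matrices = mats, labels = responders, collection = collection,
       truth = list(markers = markers, responders = responders,
                    effectD = ex$effectD, sharedVariance = rho))
}

#' Generate a Bliss-composed drug-combination plate
#'
#' Monotherapy effects follow Hill curves; the combined effect is the
#' Bliss composition of both drugs and a background-death baseline,
#' plus the interaction `beta` in true combination cells (clamped to
#' [0, 1]). Fluorescence is effect x confluence with Gaussian noise,
#' so fluorescence / confluence recovers the effect scale.
#'
#' @param config from [syntheticConfig()].
#' @param model,drugA,drugB identifiers.
#' @param beta overrides `config$combination$beta` when given.
#' @return list: `records` (combination schema), `truth`
#'   (`data.frame`: model, drugA, drugB, beta, baselineEffect).
#' @export
genCombination <- function(config = syntheticConfig(), model = "PDX01",
                           drugA = "5-FU", drugB = "olaparib",
                           beta = NULL) {
  cb <- config$combination
  if (is.null(beta)) beta <- cb$beta
  set.seed(config$seed + 404L)
  hillEff <- function(d) cb$emax * d^cb$hill / (d^cb$hill + cb$ec50^cb$hill)
  rows <- list()
  for (a in cb$dosesA) for (b in cb$dosesB) {
    eA <- hillEff(a); eB <- hillEff(b)
    e <- 1 - (1 - cb$baselineEffect) * (1 - eA) * (1 - eB)
    if (a > 0 && b > 0) e <- e + beta
    e <- min(max(e, 0), 1)
    for (r in seq_len(cb$nReplicates)) {
      conf <- cb$confluence * .unitLnorm(1, 0.02)
      fl <- max((e + stats::rnorm(1, 0, cb$sigma)) * conf, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, drugA = drugA, doseA_uM = a,
        drugB = drugB, doseB_uM = b, replicate = r,
        fluorescence = fl, confluence = conf)
    }
  }
  list(records = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = data.frame(model = model, drugA = drugA, drugB = drugB,
                          beta = beta, baselineEffect = cb$baselineEffect))
}

#' Write a complete synthetic study directory
#'
#' Emits every pipeline input (growth CSV, viability CSV + Cmax table,
#' response-annotation CSV derived from the generating truth,
#' expression TSVs, GMT collection, combination CSV) plus a `truth/`
#' subdirectory, all derived from one seed.
#'
#' @param config from [syntheticConfig()].
#' @param dir output directory (created).
#' @return named list of written paths, invisibly.
#' @export
generateStudy <- function(config = syntheticConfig(), dir) {
  dir.create(file.path(dir, "truth"), showWarnings = FALSE,
             recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  gr <- genGrowth(config)
  vb <- genViability(config)
  ex <- genExpression(config)
  cmb <- genCombination(config)
  writeResults(gr$records, p("growth.csv"))
  writeResults(gr$truth, p("truth", "growth_truth.csv"))
  writeResults(vb$records, p("viability.csv"))
  writeResults(vb$cmax, p("cmax.csv"))
  writeResults(vb$truth, p("truth", "viability_truth.csv"))
  writeResults(cmb$records, p("combination.csv"))
  writeResults(cmb$truth, p("truth", "combination_truth.csv"))
  for (pl in names(ex$matrices))
    writeExpressionMatrix(ex$matrices[[pl]],
                          p(sprintf("expression_%s.tsv", pl)))
  writeGmt(ex$collection, p("genesets.gmt"))
  writeResults(data.frame(model = names(ex$labels),
                          label = unname(ex$labels)),
               p("truth", "labels.csv"))
  writeResults(data.frame(gene = ex$truth$markers),
               p("truth", "markers.csv"))
  # response annotations on both platforms from the growth/viability truth
  matched <- sprintf("M%02d", seq_len(config$nMatched))
  pdx <- data.frame(model = gr$truth$model, drug = gr$truth$drug,
                    platform = "PDX",
                    response_value = gr$truth$expected_tc)
  pdx <- pdx[pdx$model %in% sprintf("PDX%02d", seq_len(config$nMatched)), ]
  pdx$model <- sub("PDX", "M", pdx$model)
  pd3d <- data.frame(model = sub("PD3D", "M", vb$truth$model),
                     drug = vb$truth$drug, platform = "PD3D",
                     response_value = 100 * vb$truth$viability_at_cmax)
  writeResults(rbind(pdx, pd3d), p("responses.csv"))
  invisible(list(
    growth = p("growth.csv"), viability = p("viability.csv"),
    cmax = p("cmax.csv"), combination = p("combination.csv"),
    responses = p("responses.csv"),
    expression = stats::setNames(
      file.path(dir, sprintf("expression_%s.tsv", names(ex$matrices))),
      names(ex$matrices)),
    genesets = p("genesets.gmt"), truthDir = p("truth")))
}
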