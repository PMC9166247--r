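#' Simulate a two-group bulk expression matrix with planted DE genes and hub
#' lncRNA modules
#'
#' Generates a log2-scale genes-by-samples matrix emulating a case/control
#' lung profiling study: a fraction of genes receive a group mean shift of
#' `+/-effectSize`, and each planted hub lncRNA shares a latent Gaussian
#' factor with `hubDegree` partner mRNAs so that their within-group Pearson
#' correlation is `rhoTarget`. Hubs and their partners are always part of the
#' planted DE set (all shifted upward, a concordant co-regulated module), so
#' they survive the downstream DEG filter and enter the co-expression network.
#'
#' The factor model for a module gene is
#' `x = baseline + shift * case + a*f + b*e` with `a = sigma*sqrt(rho)`,
#' `b = sigma*sqrt(1-rho)`, `f` the module factor and `e` iid noise, so the
#' within-group variance is `sigma^2` for every gene and the within-group
#' correlation of two module genes is exactly `rhoTarget`. Pooling cases and
#' controls adds the shared group shift to the covariance; the resulting
#' pooled correlation is given in closed form by [hubPartnerCorrelation()].
#'
#' @param nControl,nCase samples per group (each >= 3).
#' @param nGenes total genes; the first `nLnc` are lncRNAs, the rest mRNAs.
#' @param nLnc number of lncRNA genes.
#' @param deFrac fraction of genes planted differentially expressed, in (0,1).
#' @param effectSize log2-scale case-minus-control mean shift (absolute).
#' @param nHubs number of planted hub lncRNAs.
#' @param hubDegree partner mRNAs per hub (<= number of mRNAs).
#' @param rhoTarget within-group latent correlation between a hub and each
#'   partner, in [0,1).
#' @param sigma residual noise sd (log2 units); `sigma = 0` yields the exact
#'   noiseless limit (every planted DE gene has mean difference exactly
#'   `+/-effectSize`).
#' @param seed integer seed; identical arguments and seed reproduce the
#'   matrix bit-for-bit. The generator uses a private RNG stream and leaves
#'   the caller's RNG state untouched.
#'
#' @return a list with elements `expr`, a [SummarizedExperiment] (assay
#'   `"exprs"`; `rowData(expr)$biotype` in `lncRNA`/`mRNA`;
#'   `colData(expr)$group` in `normal`/`IPF`) and `truth`, a [BulkTruth-class].
#'
#' @examples
#' sim <- simulateBulk(nControl = 6, nCase = 6, nGenes = 50, nLnc = 5,
#'                     deFrac = 0.2, hubDegree = 8, seed = 1)
#' sim$truth
#' @importFrom SummarizedExperiment SummarizedExperiment rowData colData assay
#' @importFrom stats rnorm
#' @export
simulateBulk <- function(nControl = 12, nCase = 12, nGenes = 500, nLnc = 50,
                         deFrac = 0.2, effectSize = 2.0, nHubs = 1,
                         hubDegree = 20, rhoTarget = 0.9, sigma = 1.0,
                         seed = 1) {
  nControl <- assertCount(nControl, "nControl", min = 3L)
  nCase <- assertCount(nCase, "nCase", min = 3L)
  nGenes <- assertCount(nGenes, "nGenes", min = 2L)
  nLnc <- assertCount(nLnc, "nLnc", min = 1L)
  nHubs <- assertCount(nHubs, "nHubs", min = 0L)
  hubDegree <- assertCount(hubDegree, "hubDegree", min = 1L)
  deFrac <- assertFraction(deFrac, "deFrac")
  rhoTarget <- assertFraction(rhoTarget, "rhoTarget", openLo = FALSE)
  if (!is.numeric(effectSize) || effectSize < 0)
    stop("'effectSize' must be a non-negative number")
  if (!is.numeric(sigma) || sigma < 0)
    stop("'sigma' must be a non-negative number")
  nMrna <- nGenes - nLnc
  if (nMrna < 1L) stop("'nLnc' must be smaller than 'nGenes'")
  if (hubDegree > nMrna)
    stop(sprintf("'hubDegree' (%d) exceeds the number of available mRNAs (%d)",
                 hubDegree, nMrna))
  if (nHubs > nLnc) stop("'nHubs' exceeds 'nLnc'")
  if (nHubs * hubDegree > nMrna)
    stop("not enough mRNAs for disjoint hub modules")
  nDE <- round(deFrac * nGenes)
  if (nDE < nHubs * (1L + hubDegree))
    stop(sprintf(paste("planted DE budget (%d genes at deFrac = %g) cannot",
                       "hold %d hub(s) with %d partners each"),
                 nDE, deFrac, nHubs, hubDegree))

  lncIds <- sprintf("LNC%03d", seq_len(nLnc))
  mrnaIds <- sprintf("MRNA%04d", seq_len(nMrna))
  geneIds <- c(lncIds, mrnaIds)
  nSamples <- nControl + nCase
  isCase <- rep(c(FALSE, TRUE), c(nControl, nCase))

  res <- withSeed(seed, {
    hubs <- if (nHubs > 0) sample(lncIds, nHubs) else character()
    partnerPool <- sample(mrnaIds, nHubs * hubDegree)
    hubLncs <- stats::setNames(
      split(partnerPool, rep(seq_len(max(nHubs, 1L)),
                             each = hubDegree)[seq_along(partnerPool)])[
                               seq_len(nHubs)],
      hubs)
    committed <- c(hubs, partnerPool)
    rest <- sample(setdiff(geneIds, committed), nDE - length(committed))
    restUp <- rest[seq_len(floor(length(rest) / 2))]
    restDown <- setdiff(rest, restUp)
    deUp <- c(committed, restUp)   # hub modules concordantly up-regulated
    deDown <- restDown

    baseline <- rnorm(nGenes, mean = 7, sd = 1.5)
    shift <- numeric(nGenes)
    shift[match(deUp, geneIds)] <- effectSize
    shift[match(deDown, geneIds)] <- -effectSize

    a <- sigma * sqrt(rhoTarget)
    b <- sigma * sqrt(1 - rhoTarget)
    mat <- baseline + shift %o% as.numeric(isCase) +
      matrix(rnorm(nGenes * nSamples, sd = sigma), nGenes, nSamples)
    for (h in names(hubLncs)) {
      members <- match(c(h, hubLncs[[h]]), geneIds)
      f <- rnorm(nSamples)
      mat[members, ] <- baseline[members] +
        shift[members] %o% as.numeric(isCase) +
        a * rep(1, length(members)) %o% f +
        b * matrix(rnorm(length(members) * nSamples),
                   length(members), nSamples)
    }
    list(mat = mat, deUp = deUp, deDown = deDown, hubLncs = hubLncs)
  })

  sampleIds <- sprintf("S%02d", seq_len(nSamples))
  dimnames(res$mat) <- list(geneIds, sampleIds)
  se <- SummarizedExperiment(
    assays = list(exprs = res$mat),
    rowData = S4Vectors::DataFrame(
      biotype = rep(c("lncRNA", "mRNA"), c(nLnc, nMrna)), row.names = geneIds),
    colData = S4Vectors::DataFrame(
      group = ifelse(isCase, "IPF", "normal"), row.names = sampleIds))
  truth <- new("BulkTruth", deUp = res$deUp, deDown = res$deDown,
               hubLncs = res$hubLncs, effectSize = effectSize,
               rhoTarget = rhoTarget, sigma = sigma, seed = as.integer(seed))
  validObject(truth)
  list(expr = se, truth = truth)
}

#' Closed-form pooled hub-partner correlation of the bulk generator
#'
#' [simulateBulk()] plants `rhoTarget` as the within-group correlation of a
#' hub module. When samples of both groups are pooled (as the network stage
#' does), the shared group shift contributes to the covariance of two
#' concordantly shifted module genes, giving the pooled population
#' correlation
#' \deqn{\rho^\ast = \frac{\rho\,\sigma^2 + e^2/4}{\sigma^2 + e^2/4}}
#' for balanced groups, where `e` is the effect size. In the noiseless limit
#' (`sigma = 0`, `e > 0`) the pooled correlation is 1.
#'
#' @param rho within-group latent correlation (`rhoTarget`).
#' @param effectSize planted mean shift.
#' @param sigma residual sd.
#' @return the pooled Pearson correlation between a hub and a partner.
#' @export
hubPartnerCorrelation <- function(rho, effectSize = 2.0, sigma = 1.0) {
  d2 <- effectSize^2 / 4
  if (sigma == 0) return(if (d2 > 0) 1 else NaN)
  (rho * sigma^2 + d2) / (sigma^2 + d2)
}

#' Simulate a sparse single-cell UMI count matrix with planted low-quality
#' cells
#'
#' Generates a [SingleCellExperiment] of Poisson UMI counts drawn from
#' per-cell-type rate programs, with mitochondrial genes (symbol prefix
#' `"MT-"`), a configurable number of rare genes (detected in fewer cells
#' than `minCells`), and planted low-quality cells that violate, by
#' construction, exactly the QC threshold for their reason:
#' \describe{
#'   \item{`few_genes`}{detects fewer than `minGenes` genes;}
#'   \item{`many_genes`}{detects more than `maxGenes` genes;}
#'   \item{`high_mito`}{mitochondrial UMI fraction above `maxMito` (planted
#'     at >= 0.5 by default geometry) while passing the gene-count bounds.}
#' }
#' All other cells pass every threshold: each cell type's program guarantees
#' a detected-gene floor above `minGenes`, a support ceiling below
#' `maxGenes`, and a capped mitochondrial fraction.
#'
#' The thresholds are generator arguments so that planted violations hold at
#' any problem size; pass the same values to [qcFilter()] to recover exactly
#' the planted per-step removals.
#'
#' @param nCellsPerType named integer vector, cells per cell type.
#' @param nGenes total genes (including mitochondrial and rare genes).
#' @param nMito number of mitochondrial genes (>= 1).
#' @param nLowQuality named integer vector with any of `few_genes`,
#'   `many_genes`, `high_mito`.
#' @param nRareGenes genes planted detected in a single cell (they fail the
#'   min-cells gene filter when `minCells >= 2`).
#' @param minGenes,minCells,maxGenes,maxMito the QC thresholds the dataset is
#'   built against.
#' @param seed integer seed (private RNG stream; reproducible).
#' @return list with `sce`, a [SingleCellExperiment] (sparse `counts` assay;
#'   `colData`: `cell_type`, `condition`, `subject`; `rowData`: `symbol`,
#'   `is_mito`) and `truth`, an [SCTruth-class].
#' @examples
#' sim <- simulateSC(nLowQuality = c(few_genes = 2, high_mito = 4), seed = 1)
#' sim$truth
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom stats rexp rpois setNames
#' @export
simulateSC <- function(nCellsPerType = c(T1 = 60, T2 = 60, T3 = 60),
                       nGenes = 1000, nMito = 10,
                       nLowQuality = c(few_genes = 0, many_genes = 0,
                                       high_mito = 0),
                       nRareGenes = 5,
                       minGenes = 50, minCells = 3, maxGenes = 500,
                       maxMito = 0.30, seed = 1) {
  nGenes <- assertCount(nGenes, "nGenes", min = 10L)
  nMito <- assertCount(nMito, "nMito", min = 1L)
  nRareGenes <- assertCount(nRareGenes, "nRareGenes")
  minGenes <- assertCount(minGenes, "minGenes", min = 1L)
  minCells <- assertCount(minCells, "minCells", min = 1L)
  maxGenes <- assertCount(maxGenes, "maxGenes", min = 1L)
  maxMito <- assertFraction(maxMito, "maxMito", openLo = TRUE, openHi = FALSE)
  if (is.null(names(nCellsPerType)) || any(nCellsPerType < 1))
    stop("'nCellsPerType' must be a named vector of positive counts")
  okReasons <- c("few_genes", "many_genes", "high_mito")
  nLowQuality <- nLowQuality[nLowQuality > 0]
  if (length(nLowQuality) && !all(names(nLowQuality) %in% okReasons))
    stop("low-quality reasons must be among: ",
         paste(okReasons, collapse = ", "))
  if (minGenes > nGenes)
    stop("unattainable threshold: minGenes exceeds nGenes")
  wantMany <- sum(nLowQuality[names(nLowQuality) == "many_genes"])
  if (wantMany > 0 && maxGenes >= nGenes - nRareGenes)
    stop(paste("unattainable threshold: many_genes cells need maxGenes <",
               "nGenes - nRareGenes"))
  wantFew <- sum(nLowQuality[names(nLowQuality) == "few_genes"])
  if (wantFew > 0 && minGenes < 2L)
    stop("unattainable threshold: few_genes cells need minGenes >= 2")

  types <- names(nCellsPerType)
  nTypes <- length(types)
  coreN <- minGenes + 10L
  nRegular <- nGenes - nMito - nRareGenes
  perType <- rep(nRegular %/% nTypes, nTypes) +
    c(rep(1L, nRegular %% nTypes), rep(0L, nTypes - nRegular %% nTypes))
  if (any(perType < coreN))
    stop(sprintf(paste("program too small: each cell type needs >= %d",
                       "regular genes to guarantee the detected-gene floor;",
                       "increase nGenes or lower minGenes"), coreN))
  floorPerCell <- coreN + ceiling((max(perType) - coreN) * minCells /
                                    min(nCellsPerType))
  if (floorPerCell + nMito > maxGenes)
    stop("unattainable threshold: guaranteed detection floor reaches maxGenes")
  if (coreN + nMito > maxGenes)
    stop("unattainable threshold: high_mito support exceeds maxGenes")
  if (any(nCellsPerType < minCells))
    stop("each cell type needs at least 'minCells' cells")

  regIds <- sprintf("G%04d", seq_len(nRegular + nRareGenes))
  rareIds <- if (nRareGenes > 0) utils::tail(regIds, nRareGenes) else character()
  mitoIds <- sprintf("MT-%d", seq_len(nMito))
  geneIds <- c(regIds, mitoIds)
  onSets <- split(seq_len(nRegular), rep(seq_len(nTypes), perType))

  normType <- rep(types, nCellsPerType)
  nNormal <- length(normType)
  lqReason <- rep(names(nLowQuality), nLowQuality)
  lqType <- types[((seq_along(lqReason) - 1L) %% nTypes) + 1L]
  nCells <- nNormal + length(lqReason)
  cellIds <- sprintf("C%04d", seq_len(nCells))
  mitoRows <- nRegular + nRareGenes + seq_len(nMito)

  out <- withSeed(seed, {
    mat <- matrix(0L, nGenes, nCells)
    lambdas <- lapply(onSets, function(idx) rexp(length(idx)) + 0.3)
    # normal cells, per type
    for (t in seq_len(nTypes)) {
      cells <- which(normType == types[t])
      rows <- onSets[[t]]
      lam <- lambdas[[t]]
      cnt <- matrix(rpois(length(rows) * length(cells), lam),
                    nrow = length(rows))
      cnt[seq_len(coreN), ] <- cnt[seq_len(coreN), ] + 1L  # detection floor
      # guarantee every program gene is detected in >= minCells cells
      protected <- matrix(FALSE, length(rows), length(cells))
      protected[seq_len(coreN), ] <- TRUE
      for (j in seq_along(rows)[-seq_len(coreN)]) {
        at <- ((j - 1L + seq_len(minCells) - 1L) %% length(cells)) + 1L
        cnt[j, at] <- cnt[j, at] + 1L
        protected[j, at] <- TRUE
      }
      # hard detection ceiling: zero surplus unprotected genes so every
      # normal cell stays at or below maxGenes detected genes
      maxOn <- maxGenes - nMito
      for (cc in seq_along(cells)) {
        pos <- which(cnt[, cc] > 0L)
        excess <- length(pos) - maxOn
        if (excess > 0L) {
          victims <- rev(setdiff(pos, which(protected[, cc])))
          cnt[victims[seq_len(excess)], cc] <- 0L
        }
      }
      mat[rows, cells] <- cnt
      mito <- matrix(rpois(nMito * length(cells), 0.3), nrow = nMito)
      mito[, seq_len(min(minCells, length(cells)))] <-
        mito[, seq_len(min(minCells, length(cells)))] + 1L
      # cap the mitochondrial fraction safely below maxMito
      nm <- colSums(cnt)
      cap <- floor(0.8 * maxMito * nm / (1 - 0.8 * maxMito))
      over <- which(colSums(mito) > cap)
      for (cc in over)
        mito[, cc] <- as.integer(floor(mito[, cc] * cap[cc] /
                                         sum(mito[, cc])))
      mat[mitoRows, cells] <- mito
    }
    # rare genes: each detected in exactly one (normal) cell
    for (k in seq_len(nRareGenes)) {
      g <- nRegular + k
      mat[g, ((k - 1L) %% nNormal) + 1L] <- 1L
    }
    # planted low-quality cells
    for (i in seq_along(lqReason)) {
      cell <- nNormal + i
      rows <- onSets[[match(lqType[i], types)]]
      if (lqReason[i] == "few_genes") {
        sup <- rows[seq_len(max(1L, minGenes %/% 2L))]
        mat[sup, cell] <- 1L + rpois(length(sup), 0.5)
      } else if (lqReason[i] == "many_genes") {
        # support drawn from non-rare rows only, so rare-gene detection
        # counts stay exactly as planted
        pool <- c(seq_len(nRegular), mitoRows)
        sup <- pool[seq_len(min(maxGenes + 20L, length(pool)))]
        mat[sup, cell] <- 1L + rpois(length(sup), 1)
      } else { # high_mito
        sup <- rows[seq_len(coreN)]
        mat[sup, cell] <- 1L
        nm <- length(sup)
        # mito majority: fraction >= 0.5 and strictly above maxMito
        mMin <- max(floor(maxMito * nm / (1 - maxMito)) + 1L, nm)
        mat[mitoRows, cell] <- as.integer(ceiling(mMin / nMito)) +
          rpois(nMito, 2)
      }
    }
    mat
  })

  dimnames(out) <- list(geneIds, cellIds)
  condition <- rep_len(c("normal", "IPF"), nCells)
  sce <- SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(out, sparse = TRUE)),
    colData = S4Vectors::DataFrame(
      cell_type = c(normType, lqType),
      condition = condition,
      subject = paste0(condition, "_", rep_len(c("A", "B"), nCells)),
      row.names = cellIds),
    rowData = S4Vectors::DataFrame(
      symbol = geneIds,
      is_mito = startsWith(geneIds, "MT-"),
      row.names = geneIds))
  truth <- new("SCTruth",
               lowQualityCells = setNames(lqReason,
                                          cellIds[nNormal + seq_along(lqReason)]),
               rareGenes = rareIds,
               thresholds = list(minGenes = minGenes, minCells = minCells,
                                 maxGenes = maxGenes, maxMito = maxMito),
               seed = as.integer(seed))
  validObject(truth)
  list(sce = sce, truth = truth)
}

#' Simulate a gene-set collection over a universe
#'
#' Draws `nSets` member sets uniformly at random from `universe` (useful for
#' null-calibration experiments and for exercising the enrichment and
#' crosstalk stages when no curated GMT is supplied). Fixed sets, e.g. a
#' planted hub module, can be prepended via `include`.
#'
#' @param universe character vector of background gene ids.
#' @param nSets number of random sets.
#' @param setSize members per random set.
#' @param include optional named list of fixed member vectors.
#' @param seed integer seed.
#' @return a [GeneSetCollection-class].
#' @export
simulateGeneSets <- function(universe, nSets = 10, setSize = 20,
                             include = NULL, seed = 1) {
  nSets <- assertCount(nSets, "nSets")
  setSize <- assertCount(setSize, "setSize", min = 1L)
  if (setSize > length(universe))
    stop("'setSize' exceeds the universe size")
  sets <- withSeed(seed, {
    s <- lapply(seq_len(nSets), function(i) sample(universe, setSize))
    setNames(s, sprintf("SET%02d", seq_len(nSets)))
  })
  GeneSetCollection(c(include, sets), universe = universe)
}
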