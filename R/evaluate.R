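# Evaluation protocol: class-wise SSIM, an edge-vicinity grid mask,
# micro/macro Dice restricted to the mask regions, baseline adjustment, and
# the paired t / exact sign tests.

.boxSum <- function(M, k) {
  H <- nrow(M); W <- ncol(M)
  cs <- apply(M, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  S <- rbind(0, cbind(0, cs))
  S[(k + 1):(H + 1), (k + 1):(W + 1)] -
    S[1:(H - k + 1), (k + 1):(W + 1)] -
    S[(k + 1):(H + 1), 1:(W - k + 1)] +
    S[1:(H - k + 1), 1:(W - k + 1)]
}

#' Structural similarity index of two single-channel images
#'
#' Mean local SSIM with a uniform `winSize x winSize` sliding window,
#' unbiased (sample) variances and covariances, and the conventional
#' stabilizing constants `C1 = (0.01 * dataRange)^2`,
#' `C2 = (0.03 * dataRange)^2`. Only fully interior window positions enter
#' the mean. The constants keep the score well defined for constant
#' (zero-variance) inputs: identical constant images score 1.
#'
#' @param x,y numeric matrices of equal size, at least
#'   `winSize x winSize`.
#' @param dataRange value range of the data (1 for probability maps).
#' @param winSize odd sliding-window side, default 7.
#' @return The mean SSIM, a scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, dataRange = 1, winSize = 7) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  if (winSize %% 2 != 1 || winSize < 3)
    stop("winSize must be odd and >= 3", call. = FALSE)
  if (any(dim(x) < winSize))
    stop("images smaller than the SSIM window", call. = FALSE)
  N <- winSize^2
  ux <- .boxSum(x, winSize) / N
  uy <- .boxSum(y, winSize) / N
  covNorm <- N / (N - 1)
  vx <- covNorm * (.boxSum(x * x, winSize) / N - ux^2)
  vy <- covNorm * (.boxSum(y * y, winSize) / N - uy^2)
  vxy <- covNorm * (.boxSum(x * y, winSize) / N - ux * uy)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
       ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

#' Class-wise SSIM of two probability maps
#'
#' Computes [ssim()] separately for each class channel and returns the
#' arithmetic mean over classes — the similarity score used to compare a
#' reconstructed class-probability map with the ground truth.
#'
#' @param pred,truth [ProbabilityMap-class] objects of identical shape.
#' @param dataRange,winSize passed to [ssim()].
#' @return Scalar mean-over-classes SSIM.
#' @export
ssimClasswise <- function(pred, truth, dataRange = 1, winSize = 7) {
  pv <- probValues(pred); tv <- probValues(truth)
  stopifnot(all(dim(pv) == dim(tv)))
  C <- dim(pv)[3]
  mean(vapply(seq_len(C),
              function(ch) ssim(pv[, , ch], tv[, , ch], dataRange, winSize),
              numeric(1)))
}

#' Edge-vicinity grid mask
#'
#' Marks the pixels within `halfWidth` pixels of any interior no-overlap
#' tile boundary (the grid lines at multiples of `patch`). `TRUE` pixels are
#' the edge-vicinity region where patch-border artefacts live; `FALSE`
#' pixels are the patch-centre region. The two regions partition the image.
#'
#' @param height,width image extent in pixels.
#' @param patch tile side in pixels.
#' @param halfWidth band half-width in pixels on each side of a grid line;
#'   must be less than `patch/2`. `halfWidth = 0` gives an all-`FALSE` mask.
#' @return Logical `height x width` matrix with attributes `halfWidth` and
#'   `patch`.
#' @export
makeGridMask <- function(height, width, patch, halfWidth = 5) {
  stopifnot(halfWidth >= 0, halfWidth < patch / 2)
  band <- function(n) {
    b <- rep(FALSE, n)
    lines <- if (n > patch) seq.int(patch, n - 1L, by = patch)
             else integer(0)  # no interior tile boundary
    if (halfWidth > 0) for (r in lines) {
      lo <- max(r - halfWidth + 1L, 1L)
      hi <- min(r + halfWidth, n)
      b[lo:hi] <- TRUE
    }
    b
  }
  m <- outer(band(height), band(width), `|`)
  attr(m, "halfWidth") <- halfWidth
  attr(m, "patch") <- patch
  m
}

.diceRegion <- function(pred, truth, nClasses, absentClass) {
  if (length(pred) == 0)
    return(c(dice_micro = NA_real_, dice_macro = NA_real_))
  tp <- fp <- fn <- numeric(nClasses)
  for (c0 in seq_len(nClasses) - 1L) {
    tp[c0 + 1] <- sum(pred == c0 & truth == c0)
    fp[c0 + 1] <- sum(pred == c0 & truth != c0)
    fn[c0 + 1] <- sum(pred != c0 & truth == c0)
  }
  micro <- 2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn))
  per <- 2 * tp / (2 * tp + fp + fn)
  absent <- (tp + fp + fn) == 0
  if (absentClass == "one") per[absent] <- 1 else per <- per[!absent]
  c(dice_micro = micro, dice_macro = mean(per))
}

#' Micro and macro Dice, split by mask region
#'
#' Multiclass Dice between predicted and true label masks, computed
#' separately for the edge-vicinity (`mask == TRUE`) and patch-centre
#' regions. Micro-averaging pools true/false positives and false negatives
#' over all classes before forming `2*TP / (2*TP + FP + FN)`;
#' macro-averaging computes the per-class Dice first and averages the
#' ratios.
#'
#' @param predLabels,truthLabels integer matrices of labels `0..C-1` (see
#'   [asLabelMask()]).
#' @param mask logical matrix from [makeGridMask()], or `NULL` to score the
#'   whole image as a single `"all"` region.
#' @param nClasses number of classes; defaults to the number observed.
#' @param absentClass what a class absent from both prediction and truth in
#'   a region contributes to the macro mean: `"one"` (correct absence
#'   scores 1, default) or `"skip"` (dropped from the mean).
#' @return `data.frame` with columns `region`, `dice_micro`, `dice_macro`.
#' @export
diceScores <- function(predLabels, truthLabels, mask = NULL,
                       nClasses = NULL, absentClass = c("one", "skip")) {
  absentClass <- match.arg(absentClass)
  stopifnot(all(dim(predLabels) == dim(truthLabels)))
  if (is.null(nClasses))
    nClasses <- max(predLabels, truthLabels) + 1L
  if (is.null(mask)) {
    s <- .diceRegion(as.vector(predLabels), as.vector(truthLabels),
                     nClasses, absentClass)
    return(data.frame(region = "all", dice_micro = s[1], dice_macro = s[2],
                      row.names = NULL))
  }
  stopifnot(all(dim(mask) == dim(predLabels)))
  out <- lapply(c(centre = FALSE, edge_vicinity = TRUE), function(v) {
    .diceRegion(predLabels[mask == v], truthLabels[mask == v],
                nClasses, absentClass)
  })
  data.frame(region = names(out),
             dice_micro = vapply(out, `[[`, numeric(1), 1L),
             dice_macro = vapply(out, `[[`, numeric(1), 2L),
             row.names = NULL)
}

#' Baseline-adjust a score table
#'
#' Adds (or recomputes) the `adjusted` column: each method's raw score minus
#' the `no_overlap` baseline's raw score on the same image, metric and
#' region. This isolates the effect of the recombination strategy from the
#' predictor's own accuracy; the baseline's adjusted score is 0 by
#' construction.
#'
#' @param table `data.frame` with columns `image_id`, `method`, `metric`,
#'   `region`, `raw`.
#' @param baseline the baseline method name (default `"no_overlap"`).
#' @return The table with an `adjusted` column.
#' @export
adjustedScores <- function(table, baseline = "no_overlap") {
  need <- c("image_id", "method", "metric", "region", "raw")
  stopifnot(all(need %in% names(table)))
  base <- table[table$method == baseline,
                c("image_id", "metric", "region", "raw")]
  if (nrow(base) == 0)
    stop("no rows for baseline method '", baseline, "'", call. = FALSE)
  names(base)[names(base) == "raw"] <- ".baseline"
  merged <- merge(table, base, by = c("image_id", "metric", "region"),
                  sort = FALSE)
  merged$adjusted <- merged$raw - merged$.baseline
  merged$.baseline <- NULL
  merged[order(merged$image_id, merged$method, merged$metric,
               merged$region), ]
}

#' Paired t-test on per-image score differences
#'
#' One-sample t-test of the paired differences against zero, `df = n - 1`,
#' two-sided p-value. Zero-variance differences are reported as degenerate
#' (t = 0, p = 1 when all differences are zero; infinite t, p = 0
#' otherwise) rather than `NaN`.
#'
#' @param differences numeric vector of per-image differences, length >= 2.
#' @return List with `statistic`, `df`, `p.value`, `mean`, `sd`,
#'   `degenerate`.
#' @export
pairedTTest <- function(differences) {
  n <- length(differences)
  if (n < 2) stop("need at least two paired differences", call. = FALSE)
  m <- mean(differences); s <- stats::sd(differences)
  if (s < .Machine$double.eps * max(1, abs(m))) {
    return(list(statistic = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1L, p.value = if (m == 0) 1 else 0,
                mean = m, sd = s, degenerate = TRUE))
  }
  tt <- stats::t.test(differences)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean = m, sd = s, degenerate = FALSE)
}

#' Exact sign test on per-image score differences
#'
#' Two-sided exact binomial test on the counts of positive and negative
#' differences (ties dropped), i.e. the exact sign test of the null that
#' positive and negative differences are equally likely.
#'
#' @param differences numeric vector of per-image differences.
#' @return List with `positive`, `negative`, `ties`, `p.value`.
#' @export
exactSignTest <- function(differences) {
  pos <- sum(differences > 0)
  neg <- sum(differences < 0)
  ties <- sum(differences == 0)
  if (pos + neg == 0)
    stop("all differences are ties; the sign test is undefined",
         call. = FALSE)
  bt <- stats::binom.test(pos, pos + neg, p = 0.5,
                          alternative = "two.sided")
  list(positive = pos, negative = neg, ties = ties, p.value = bt$p.value)
}

#' Benchmark the six reconstruction methods on synthetic scenes
#'
#' For each of `nSeeds` seeded scenes: generate the three-class ground
#' truth, build the border-degraded predictor, reconstruct with every
#' requested method, and score each reconstruction with class-wise SSIM
#' (whole image) and micro/macro Dice restricted to the patch-centre and
#' edge-vicinity regions of the grid mask. Scores are then baseline-adjusted
#' against `no_overlap`, and all method pairs are compared with a paired
#' t-test and an exact sign test on the per-image raw SSIM differences.
#'
#' Because the simulated predictor is deterministic per (seed, origin), all
#' methods see identical patch predictions within an image — the comparison
#' is paired exactly as in a real benchmark where one trained network feeds
#' every recombination strategy.
#'
#' @param nSeeds number of benchmark images (scenes).
#' @param scene a [SceneSpec-class] template; its seed is replaced by
#'   `baseSeed + 0 .. nSeeds-1` per image.
#' @param profile an [ArtefactProfile-class] template; per-image seed
#'   handled likewise.
#' @param methods subset of [reconstructionMethods()]; must include the
#'   baseline.
#' @param patch patch side in pixels.
#' @param maskHalfWidth half-width of the edge-vicinity band, pixels.
#' @param baseSeed first image seed.
#' @return List with `scores` (long `data.frame`: `image_id`, `method`,
#'   `metric`, `region`, `raw`, `adjusted`), `tests` (per method pair:
#'   matrices of paired-t and sign-test p-values and mean differences on
#'   raw SSIM), and `params`.
#' @export
runBenchmark <- function(nSeeds = 14, scene = SceneSpec(),
                         profile = ArtefactProfile(),
                         methods = reconstructionMethods(), patch = 128,
                         maskHalfWidth = 5, baseSeed = scene@seed) {
  methods <- match.arg(methods, .METHODS, several.ok = TRUE)
  if (!"no_overlap" %in% methods)
    stop("methods must include the 'no_overlap' baseline", call. = FALSE)
  mask <- makeGridMask(scene@height, scene@width, patch, maskHalfWidth)
  rows <- list()
  for (s in seq_len(nSeeds)) {
    seed_s <- as.integer(baseSeed + s - 1L)
    sc <- generateScene(new("SceneSpec", height = scene@height,
                            width = scene@width, nBlobs = scene@nBlobs,
                            radiusRange = scene@radiusRange,
                            edgeBand = scene@edgeBand, seed = seed_s))
    prof_s <- new("ArtefactProfile", baseNoise = profile@baseNoise,
                  edgeNoise = profile@edgeNoise, profile = profile@profile,
                  softness = profile@softness,
                  seed = as.integer(profile@seed + 7919L * (s - 1L)))
    predictor <- noisyEdgePredictor(sc$truth, prof_s)
    for (method in methods) {
      # the pyramidal border-ring fill is expected here; keep the loop quiet
      rec <- suppressMessages(
        reconstructWith(sc$image, predictor, method, patch))
      sv <- ssimClasswise(rec, sc$truth)
      dice <- diceScores(asLabelMask(rec), sc$labels, mask, nClasses = 3L)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = s, method = method,
        metric = c("ssim", rep(c("dice_micro", "dice_macro"), each = 2)),
        region = c("all", rep(dice$region, times = 2)),
        raw = c(sv, dice$dice_micro, dice$dice_macro))
    }
  }
  scores <- adjustedScores(do.call(rbind, rows))
  list(scores = scores,
       tests = pairwiseTests(scores, metric = "ssim", region = "all"),
       params = list(nSeeds = nSeeds, patch = patch,
                     maskHalfWidth = maskHalfWidth,
                     scene = scene, profile = profile))
}

#' Pairwise method comparison matrices
#'
#' For every ordered pair of methods, the paired t-test and exact sign test
#' on the per-image differences (method A minus method B) of the chosen
#' metric/region — the benchmark's significance matrices in tabular form.
#'
#' @param scores the `scores` table from [runBenchmark()].
#' @param metric,region which score to compare.
#' @param value compare `"raw"` scores (default; differences are identical
#'   for `"adjusted"` except against the baseline itself).
#' @return List of matrices `t_p`, `sign_p`, `mean_diff` (methods x
#'   methods).
#' @export
pairwiseTests <- function(scores, metric = "ssim", region = "all",
                          value = "raw") {
  sub <- scores[scores$metric == metric & scores$region == region, ]
  methods <- unique(sub$method)
  k <- length(methods)
  tp <- sp <- md <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  wide <- stats::reshape(sub[, c("image_id", "method", value)],
                         idvar = "image_id", timevar = "method",
                         direction = "wide")
  vals <- as.matrix(wide[, -1, drop = FALSE])
  colnames(vals) <- sub("^.*\\.", "", colnames(vals))
  for (a in methods) for (b in methods) {
    if (a == b) next
    d <- vals[, a] - vals[, b]
    md[a, b] <- mean(d)
    tp[a, b] <- pairedTTest(d)$p.value
    sp[a, b] <- tryCatch(exactSignTest(d)$p.value,
                         error = function(e) NA_real_)
  }
  list(t_p = tp, sign_p = sp, mean_diff = md)
}
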