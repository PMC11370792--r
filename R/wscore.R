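#' Fit the normative covariate model on healthy controls
#'
#' Performs per-unit ordinary least squares of grey-matter values on the
#' declared covariates (intercept always included; categorical covariates
#' are one-hot encoded with the first level as reference). The residual
#' standard deviation per unit uses the unbiased n - p - 1 denominator for
#' p covariate terms. Units whose residual SD is zero (up to a
#' scale-aware floating-point tolerance) are flagged as degenerate and
#' excluded from the model.
#'
#' @param controls data.frame of control subjects: covariate columns plus
#'   one numeric column per unit.
#' @param covariates character vector of covariate column names; may be
#'   empty for an intercept-only model.
#' @param unitCols unit (voxel/parcel) column names; default: all numeric
#'   columns not named in `covariates` and not obvious id columns
#'   ("subjectId", "group").
#' @return a [ControlModel-class].
#' @examples
#' g <- makeGeometry(10, "grid", seed = 1)
#' coh <- makeCohort(g, 50, 0, list(age = list(mean = 70, sd = 8, beta = -0.01)),
#'                   seed = 2)
#' fitControlModel(coh$subjects, "age")
#' @export
fitControlModel <- function(controls, covariates, unitCols = NULL) {
  if (is.null(unitCols)) {
    cand <- setdiff(names(controls), c(covariates, "subjectId", "group"))
    unitCols <- cand[vapply(controls[cand], is.numeric, logical(1))]
  }
  if (any(!covariates %in% names(controls)))
    stop("missing covariate column(s)")
  covdf <- controls[, covariates, drop = FALSE]
  if (anyNA(covdf)) stop("missing covariate values")
  n <- nrow(controls)
  if (n < length(covariates) + 2)
    stop("underdetermined model: too few controls for covariate count")
  X <- buildDesign(covdf)
  if (qr(X)$rank < ncol(X))
    stop("collinear covariates: design matrix is rank deficient")
  Y <- as.matrix(controls[, unitCols, drop = FALSE])
  fit <- lm.fit(X, Y)
  resid <- as.matrix(fit$residuals)
  dfres <- n - ncol(X)
  if (dfres < 1) stop("underdetermined model: no residual degrees of freedom")
  sde <- sqrt(colSums(resid^2) / dfres)
  # scale-aware zero test: an exactly deterministic unit still leaves
  # floating-point residuals of order eps * |values|
  tol <- 1e-8 * pmax(apply(Y, 2, function(y) max(abs(y))), 1)
  degen <- unitCols[sde <= tol]
  keep <- sde > tol
  xlev <- lapply(covdf[vapply(covdf, function(x) is.factor(x) || is.character(x),
                              logical(1))],
                 function(x) levels(factor(x)))
  new("ControlModel",
      units = unitCols[keep],
      coefficients = as.matrix(fit$coefficients)[, keep, drop = FALSE],
      sde = unname(sde[keep]),
      covariates = covariates,
      xlevels = xlev,
      degenerate = degen)
}

# One-hot design matrix with intercept; factor levels from xlevels when
# scoring new subjects so the encoding matches the training design.
buildDesign <- function(covdf, xlevels = NULL) {
  if (ncol(covdf) == 0)
    return(matrix(1, nrow(covdf), 1, dimnames = list(NULL, "(Intercept)")))
  for (nm in names(covdf)) {
    if (is.character(covdf[[nm]]) || is.factor(covdf[[nm]])) {
      lev <- if (!is.null(xlevels) && nm %in% names(xlevels)) xlevels[[nm]]
             else levels(factor(covdf[[nm]]))
      bad <- !covdf[[nm]] %in% lev
      if (any(bad)) stop("schema mismatch: unknown level in covariate ", nm)
      covdf[[nm]] <- factor(covdf[[nm]], levels = lev)
    }
  }
  model.matrix(~ ., data = covdf)
}

#' Convert subject grey-matter values to a W-score map
#'
#' W = (Raw - Expected) / SDe per unit, where Expected comes from the
#' control model applied to the subject's covariates and SDe is the
#' model's residual standard deviation. By default the score is
#' sign-flipped (`atrophyPositive = TRUE`) so that LOWER grey matter than
#' expected yields HIGHER W, i.e. higher W means more severe atrophy.
#'
#' @param subject one-row data.frame (or list) with the model's covariates
#'   and the unit value columns.
#' @param model a [ControlModel-class].
#' @param atrophyPositive flip the sign so atrophy is positive
#'   (default TRUE).
#' @param label label for the returned map (default the subjectId column if
#'   present).
#' @return a [WMap-class] over the model's retained units.
#' @export
computeWMap <- function(subject, model, atrophyPositive = TRUE, label = NULL) {
  subject <- as.data.frame(subject)
  if (nrow(subject) != 1) stop("computeWMap expects a single subject row")
  miss <- setdiff(model@covariates, names(subject))
  if (length(miss))
    stop("schema mismatch: missing covariate(s): ", paste(miss, collapse = ", "))
  missU <- setdiff(model@units, names(subject))
  if (length(missU))
    stop("schema mismatch: missing unit column(s)")
  X <- buildDesign(subject[, model@covariates, drop = FALSE], model@xlevels)
  expected <- as.vector(X %*% model@coefficients)
  raw <- as.numeric(subject[, model@units])
  w <- (raw - expected) / model@sde
  if (atrophyPositive) w <- -w
  if (is.null(label))
    label <- if ("subjectId" %in% names(subject)) as.character(subject$subjectId)
             else "subject"
  new("WMap", unitId = model@units, w = w, label = label)
}

#' Compute W-score maps for every row of a subject table
#'
#' @inheritParams computeWMap
#' @param subjects data.frame, one subject per row.
#' @return list of [WMap-class], named by subjectId when present.
#' @export
computeWMaps <- function(subjects, model, atrophyPositive = TRUE) {
  maps <- lapply(seq_len(nrow(subjects)), function(i)
    computeWMap(subjects[i, , drop = FALSE], model, atrophyPositive))
  if ("subjectId" %in% names(subjects)) names(maps) <- subjects$subjectId
  maps
}

#' Average voxel-level W-scores within parcels
#'
#' Parcel value = arithmetic mean of member-unit W; units labelled NA or
#' "unassigned" are ignored.
#'
#' @param wmap a [WMap-class] at the finer (voxel) level.
#' @param parcelLabels named character: unit id -> parcel id (NA or
#'   "unassigned" to drop a unit).
#' @param parcels optional parcel universe; a listed parcel that receives
#'   no units is an error.
#' @return a [WMap-class] at parcel level.
#' @export
aggregateToParcels <- function(wmap, parcelLabels, parcels = NULL) {
  lab <- parcelLabels[wmap@unitId]
  if (anyNA(match(wmap@unitId, names(parcelLabels))))
    stop("every unit needs a parcel label (use NA/'unassigned' to drop)")
  keep <- !is.na(lab) & lab != "unassigned"
  means <- tapply(wmap@w[keep], lab[keep], mean)
  if (!is.null(parcels)) {
    empty <- setdiff(parcels, names(means))
    if (length(empty))
      stop("empty parcel: ", paste(empty, collapse = ", "))
    means <- means[parcels]
  }
  new("WMap", unitId = names(means), w = as.numeric(means), label = wmap@label)
}

#' Element-wise average of W-score maps
#'
#' @param wmaps non-empty list of [WMap-class] sharing unit ids.
#' @param label label for the averaged map.
#' @return a [WMap-class].
#' @export
groupAverage <- function(wmaps, label = "group") {
  if (!length(wmaps)) stop("invalid argument: empty map list")
  ids <- wmaps[[1]]@unitId
  M <- vapply(wmaps, function(m) {
    if (!identical(m@unitId, ids)) stop("maps do not share unit ids")
    m@w
  }, numeric(length(ids)))
  new("WMap", unitId = ids, w = rowMeans(as.matrix(M)), label = label)
}
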