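#' Predictor policy for a species group
#'
#' Candidate predictors, an ecological priority ranking (a total order;
#' earlier = more relevant, survives collinearity conflicts), and the
#' collinearity thresholds. The three presets encode the group-specific
#' choices used for deep-sea taxa: scleractinians see aragonite
#' saturation, octocorals calcite saturation (reflecting their different
#' skeletal mineralogy), corals never see depth, dissolved oxygen or pH;
#' fishes see depth and dissolved oxygen but never pH or saturation
#' states.
#'
#' @param group `"scleractinian"`, `"octocoral"`, `"fish"`, or
#'   `"custom"`.
#' @param candidates,priority Character vectors (priority must be a
#'   permutation of candidates); filled from the preset when omitted.
#' @param rho_threshold Spearman cut-off above which one of a pair is
#'   dropped (default 0.85).
#' @param vif_threshold Variance-inflation cut-off (default 10).
#' @return Object of class `bn_policy`.
#' @export
predictor_policy <- function(group = c("scleractinian", "octocoral",
                                       "fish", "custom"),
                             candidates = NULL, priority = NULL,
                             rho_threshold = 0.85, vif_threshold = 10) {
  group <- match.arg(group)
  preset <- switch(group,
    scleractinian = c("omega_ar", "temp", "poc_seafloor", "slope", "bpi",
                      "depth"),
    octocoral = c("omega_cal", "temp", "poc_seafloor", "slope", "bpi",
                  "depth"),
    fish = c("depth", "temp", "DO", "poc_seafloor", "slope", "bpi"),
    custom = NULL)
  if (is.null(candidates)) candidates <- preset
  if (is.null(priority)) priority <- candidates
  if (is.null(candidates))
    stop("custom policies must supply candidates")
  if (!setequal(candidates, priority) ||
      length(priority) != length(candidates))
    stop("priority must be a total order on the candidates")
  structure(list(group = group, candidates = candidates,
                 priority = priority, rho_threshold = rho_threshold,
                 vif_threshold = vif_threshold),
            class = "bn_policy")
}

#' Spearman correlation matrix of training covariates
#'
#' @param table Training `data.frame`.
#' @param vars Numeric columns to correlate (>= 3 rows required).
#' @return Symmetric matrix with unit diagonal.
#' @export
spearman_matrix <- function(table, vars) {
  stopifnot(nrow(table) >= 3)
  m <- as.matrix(table[, vars, drop = FALSE])
  const <- vars[apply(m, 2, function(x) stats::sd(x) == 0)]
  if (length(const))
    stop("constant column(s): ", paste(const, collapse = ", "))
  stats::cor(m, method = "spearman")
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate `j` on the
#' others. A perfectly collinear covariate is reported as `Inf` rather
#' than raising an error.
#'
#' @param table Training `data.frame`.
#' @param vars Covariate columns (`nrow > length(vars) + 1`).
#' @return Named numeric vector of VIFs (all >= 1, possibly `Inf`).
#' @export
vif <- function(table, vars) {
  stopifnot(nrow(table) > length(vars) + 1)
  if (length(vars) < 2) return(stats::setNames(rep(1, length(vars)), vars))
  m <- as.data.frame(table[, vars, drop = FALSE])
  out <- vapply(vars, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(vars, v), response = v),
                     data = m)
    r2 <- suppressWarnings(summary(fit)$r.squared) # perfect fit -> Inf sentinel
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  pmax(out, 1)
}

#' Collinearity-screened predictor selection
#'
#' Two passes, both resolved by the policy's ecological priority. First,
#' for every pair with `|Spearman rho|` above the threshold the
#' lower-priority member is dropped (processed in descending `|rho|`;
#' already-dropped variables cannot trigger further drops). Second,
#' VIFs are recomputed and the highest-VIF variable (priority breaking
#' ties) is dropped until all VIFs are at or below the threshold. Every
#' drop is logged with its trigger.
#'
#' @param policy A `bn_policy`.
#' @param table Training `data.frame` containing the candidate columns.
#' @return List with `retained` (character, in priority order) and
#'   `log` (`data.frame` of drops: variable, trigger, statistic, partner).
#' @export
select_predictors <- function(policy, table) {
  vars <- policy$candidates
  stopifnot(all(vars %in% names(table)))
  rank_of <- stats::setNames(seq_along(policy$priority), policy$priority)
  log <- data.frame(variable = character(0), trigger = character(0),
                    statistic = numeric(0), partner = character(0),
                    stringsAsFactors = FALSE)
  rho <- spearman_matrix(table, vars)
  pairs <- which(upper.tri(rho) & abs(rho) > policy$rho_threshold,
                 arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(abs(rho[pairs]), decreasing = TRUE)
    dropped <- character(0)
    for (k in ord) {
      a <- vars[pairs[k, 1]]; b <- vars[pairs[k, 2]]
      if (a %in% dropped || b %in% dropped) next
      loser <- if (rank_of[a] > rank_of[b]) a else b
      winner <- setdiff(c(a, b), loser)
      dropped <- c(dropped, loser)
      log <- rbind(log, data.frame(variable = loser, trigger = "spearman",
                                   statistic = rho[pairs[k, 1], pairs[k, 2]],
                                   partner = winner))
    }
    vars <- setdiff(vars, dropped)
  }
  repeat {
    if (length(vars) < 2) break
    v <- vif(table, vars)
    if (all(v <= policy$vif_threshold)) break
    worst <- max(v)
    cand <- names(v)[v >= worst - 1e-9]
    loser <- cand[which.max(rank_of[cand])]
    log <- rbind(log, data.frame(variable = loser, trigger = "vif",
                                 statistic = unname(v[loser]), partner = NA))
    vars <- setdiff(vars, loser)
  }
  if (!length(vars)) stop("collinearity screening dropped every candidate")
  list(retained = policy$priority[policy$priority %in% vars], log = log)
}
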