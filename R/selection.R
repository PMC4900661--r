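# Hazel selection indices. The index I = b'x on the measured (index)
# traits is chosen to maximize its correlation with the aggregate
# genotype H = w'g over the breeding-goal traits: b = P^-1 G w, where P
# is the phenotypic covariance of the index traits, G the genetic
# covariance between index and goal traits, and C the genetic covariance
# of the goal traits. Economic weights are expressed in monetary units
# per genetic standard deviation, so w_i = m_i / sigma_g(i).

#' Define a selection-index scenario
#'
#' @param index_traits Ordered subset of traits measured for selection.
#' @param goal_traits Ordered subset in the breeding goal (default: all
#'   three canonical traits — the goal always spans the full trait set in
#'   the stock scenarios, only the index varies).
#' @param monetary Named (or goal-ordered) vector of monetary units per
#'   genetic standard deviation for each goal trait (default all 1).
#' @param intensity Selection intensity `i` (default 1.75, the
#'   standardized differential for selecting the top 10%).
#' @param name Optional scenario label.
#' @return Object of class `mt_index_scenario`.
#' @examples
#' index_scenario(c("SOC", "W100S"))
#' @export
index_scenario <- function(index_traits,
                           goal_traits = names(trait_set()),
                           monetary = NULL,
                           intensity = 1.75,
                           name = NULL) {
  index_traits <- match_traits(index_traits)
  goal_traits <- match_traits(goal_traits)
  if (!length(index_traits) || !length(goal_traits))
    stop("index and goal trait sets must be non-empty", call. = FALSE)
  if (!(is.numeric(intensity) && length(intensity) == 1L && intensity > 0))
    stop("selection intensity must be a positive number", call. = FALSE)
  if (is.null(monetary)) monetary <- setNames(rep(1, length(goal_traits)), goal_traits)
  if (is.null(names(monetary))) {
    if (length(monetary) != length(goal_traits))
      stop("monetary must have one value per goal trait", call. = FALSE)
    names(monetary) <- goal_traits
  }
  if (!all(goal_traits %in% names(monetary)))
    stop("monetary must name every goal trait", call. = FALSE)
  structure(list(index_traits = index_traits, goal_traits = goal_traits,
                 monetary = monetary[goal_traits], intensity = intensity,
                 name = if (is.null(name)) paste(index_traits, collapse = "+") else name),
            class = "mt_index_scenario")
}

#' Economic weights per unit of genotypic value
#'
#' Converts monetary units expressed per genetic standard deviation into
#' weights per trait unit: `w_i = m_i / sqrt(G0[i, i])`.
#'
#' @param monetary Named vector of monetary units, one per goal trait.
#' @param G0 Genetic covariance matrix (named, canonical order).
#' @param goal_traits Goal traits; default the names of `monetary`.
#' @return Named weight vector over the goal traits.
#' @examples
#' economic_weights(c(W100S = 1, SOC = 1, PEC = 1), reference_covariances()$G0)
#' @export
economic_weights <- function(monetary, G0, goal_traits = names(monetary)) {
  goal_traits <- match_traits(goal_traits, rownames(G0))
  vg <- diag(G0)[goal_traits]
  if (any(vg <= 0))
    stop("goal-trait genetic variances must be positive", call. = FALSE)
  setNames(as.numeric(monetary[goal_traits]) / sqrt(vg), goal_traits)
}

#' Assemble the index matrices P, G and C
#'
#' `P`: phenotypic covariance (`G0 + R0`) restricted to the index traits;
#' `G`: genetic covariance of the index traits (rows) with the goal
#' traits (columns); `C`: genetic covariance among the goal traits.
#'
#' @param scn An [index_scenario()].
#' @param G0,R0 Genetic and residual trait covariance matrices with trait
#'   dimnames.
#' @return List with matrices `P`, `G`, `C`.
#' @export
build_index_matrices <- function(scn, G0, R0) {
  stopifnot(inherits(scn, "mt_index_scenario"))
  tr <- rownames(G0)
  if (is.null(tr) || is.null(rownames(R0)))
    stop("G0 and R0 must carry trait dimnames", call. = FALSE)
  it <- match_traits(scn$index_traits, tr)
  gt <- match_traits(scn$goal_traits, tr)
  P_full <- phenotypic_cov(G0, R0)
  list(P = P_full[it, it, drop = FALSE],
       G = G0[it, gt, drop = FALSE],
       C = G0[gt, gt, drop = FALSE])
}

#' Solve a Hazel selection index
#'
#' Computes the index coefficients `b = P^-1 G w`, the index and
#' aggregate-genotype standard deviations `sigma_I = sqrt(b'Pb)` and
#' `sigma_H = sqrt(w'Cw)`, the index accuracy `R_IH = sigma_I / sigma_H`,
#' the monetary gain per generation `delta_G = i * R_IH * sigma_H`, and
#' the expected per-goal-trait response `S = (i / sigma_I) * G'b` (trait
#' units per generation).
#'
#' @param scn An [index_scenario()].
#' @param G0,R0 Genetic and residual covariance matrices (trait dimnames
#'   required).
#' @return Object of class `mt_index`: list with `b`, `w`, `sigma_I`,
#'   `sigma_H`, `R_IH`, `delta_G`, `S`, `scenario`, and the matrices used.
#' @examples
#' ref <- reference_covariances()
#' solve_index(index_scenario("SOC"), ref$G0, ref$R0)
#' @export
solve_index <- function(scn, G0, R0) {
  m <- build_index_matrices(scn, G0, R0)
  w <- economic_weights(scn$monetary, G0, scn$goal_traits)
  if (rcond(m$P) < 1e-12)
    stop("index phenotypic covariance matrix P is numerically singular", call. = FALSE)
  b <- drop(solve(m$P, m$G %*% w))
  names(b) <- scn$index_traits
  sigma_I <- sqrt(drop(crossprod(b, m$P %*% b)))
  sigma_H <- sqrt(drop(crossprod(w, m$C %*% w)))
  if (sigma_H <= 0) stop("aggregate genotype has zero variance", call. = FALSE)
  R_IH <- sigma_I / sigma_H
  delta_G <- scn$intensity * R_IH * sigma_H
  S <- drop(scn$intensity / sigma_I * crossprod(m$G, b))
  names(S) <- scn$goal_traits
  structure(list(b = b, w = w, sigma_I = sigma_I, sigma_H = sigma_H,
                 R_IH = R_IH, delta_G = delta_G, S = S,
                 scenario = scn, matrices = m),
            class = "mt_index")
}

#' @export
print.mt_index <- function(x, digits = 4, ...) {
  cat(sprintf("Hazel selection index [%s] (goal: %s; i = %g)\n",
              x$scenario$name, paste(x$scenario$goal_traits, collapse = ", "),
              x$scenario$intensity))
  cat("b:\n"); print(round(x$b, digits))
  cat(sprintf("sigma_I = %.4f, sigma_H = %.4f, R_IH = %.4f, delta_G = %.4f\n",
              x$sigma_I, x$sigma_H, x$R_IH, x$delta_G))
  cat("expected response per generation:\n"); print(round(x$S, digits))
  invisible(x)
}

#' Stock scenarios and weight sets of the jatropha study design
#'
#' Three nested index scenarios (SOC alone; SOC + W100S; all three
#' traits, goal always all three) and three monetary-weight sets
#' (`w1` all 1; `w2` SOC doubled; `w3` SOC 4, W100S 2, PEC 1).
#'
#' @return `default_scenarios()`: named list of index-trait vectors;
#'   `default_weights()`: named list of monetary-unit vectors.
#' @export
default_scenarios <- function() {
  list(`1` = "SOC", `2` = c("SOC", "W100S"), `3` = c("SOC", "W100S", "PEC"))
}

#' @rdname default_scenarios
#' @export
default_weights <- function() {
  list(w1 = c(W100S = 1, SOC = 1, PEC = 1),
       w2 = c(W100S = 1, SOC = 2, PEC = 1),
       w3 = c(W100S = 2, SOC = 4, PEC = 1))
}

#' Evaluate all scenario-by-weight combinations
#'
#' Solves every combination of index scenario and monetary-weight set and
#' returns a report shaped like the study's gain table: accuracy,
#' monetary gain, and per-goal-trait expected response (columns in goal
#' order SOC, W100S, PEC).
#'
#' @param G0,R0 Genetic and residual covariance matrices (trait
#'   dimnames required).
#' @param scenarios Named list of index-trait vectors.
#' @param weights Named list of monetary-unit vectors.
#' @param intensity Selection intensity (default 1.75).
#' @return `data.frame` with columns `weight_set`, `scenario`,
#'   `index_traits`, `R_IH`, `delta_G`, `S_SOC`, `S_W100S`, `S_PEC`.
#' @examples
#' ref <- reference_covariances()
#' run_scenarios(ref$G0, ref$R0)
#' @export
run_scenarios <- function(G0, R0,
                          scenarios = default_scenarios(),
                          weights = default_weights(),
                          intensity = 1.75) {
  rows <- list()
  for (wn in names(weights)) for (sn in names(scenarios)) {
    scn <- index_scenario(scenarios[[sn]], monetary = weights[[wn]],
                          intensity = intensity, name = sn)
    res <- solve_index(scn, G0, R0)
    rows[[length(rows) + 1L]] <- data.frame(
      weight_set = wn, scenario = sn,
      index_traits = paste(scn$index_traits, collapse = "+"),
      R_IH = res$R_IH, delta_G = res$delta_G,
      S_SOC = res$S[["SOC"]], S_W100S = res$S[["W100S"]],
      S_PEC = res$S[["PEC"]], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Rank families on a solved index
#'
#' Scores each family as `b' x` on its index-trait genotypic values,
#' sorts in descending score with ties broken by ascending family ID, and
#' flags the top `ceiling(top_fraction * n)` families as selected.
#'
#' @param gv Matrix of posterior-mean genotypic values (rownames =
#'   family IDs, columns named by trait), or phenotypic deviations if the
#'   classical phenotype-based usage is wanted.
#' @param result An [solve_index()] object.
#' @param top_fraction Selected fraction (default 0.10).
#' @return `data.frame` with columns `rank`, `family_id`, `score`,
#'   `selected`.
#' @export
rank_families <- function(gv, result, top_fraction = 0.10) {
  stopifnot(inherits(result, "mt_index"))
  gv <- as.matrix(gv)
  it <- result$scenario$index_traits
  if (!all(it %in% colnames(gv)))
    stop("genotypic-value matrix does not cover the index traits", call. = FALSE)
  fam <- rownames(gv)
  if (is.null(fam)) fam <- as.character(seq_len(nrow(gv)))
  score <- drop(gv[, it, drop = FALSE] %*% result$b)
  ord <- order(-score, fam)
  n_sel <- min(nrow(gv), ceiling(top_fraction * nrow(gv)))
  data.frame(rank = seq_len(nrow(gv)), family_id = fam[ord],
             score = unname(score[ord]),
             selected = seq_len(nrow(gv)) <= n_sel,
             stringsAsFactors = FALSE)
}
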