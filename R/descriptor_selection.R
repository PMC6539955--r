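#' Pearson correlation matrix with significance stars
#'
#' Product-moment correlations between the response (listed first) and each
#' descriptor, over a chosen compound subset. Significance uses the two-tailed
#' t-test for a correlation coefficient, t = r * sqrt(n - 2) / sqrt(1 - r^2)
#' on n - 2 degrees of freedom: one star for p < 0.05, two for p < 0.01.
#'
#' @param response named numeric vector (names are compound ids).
#' @param descriptors descriptor table with a `compound_id` column, or a
#'   numeric matrix with compound ids as row names.
#' @param ids compound ids to use (default: all ids of `response`). At least 3.
#' @param response_label label for the response row/column.
#' @return an object of class `correlation_matrix`: list with `labels`, `r`
#'   (symmetric correlation matrix), `p` (two-tailed p-values), `stars`
#'   (`""`, `"*"`, `"**"`) and `n`.
#' @export
#' @examples
#' desc <- load_fixture("descriptors")
#' y <- with(load_fixture("qsar_results"),
#'           setNames(ic50_experimental, compound_id))
#' cm <- pearson_matrix(y, desc, ids = default_split()$train_ids)
#' cm$r["IC50", "vsurf_DW23"]
pearson_matrix <- function(response, descriptors, ids = names(response),
                           response_label = "IC50") {
  ids <- as.character(ids)
  if (length(ids) < 3) {
    stop("pearson_matrix: need at least 3 compounds", call. = FALSE)
  }
  if (is.data.frame(descriptors) && "compound_id" %in% names(descriptors)) {
    X <- as.matrix(descriptors[match(ids, as.character(descriptors$compound_id)),
                               setdiff(names(descriptors), "compound_id"),
                               drop = FALSE])
  } else {
    X <- as.matrix(descriptors)[ids, , drop = FALSE]
  }
  y <- response[ids]
  if (anyNA(X) || anyNA(y)) {
    stop("pearson_matrix: id(s) missing from response or descriptor table",
         call. = FALSE)
  }
  M <- cbind(stats::setNames(data.frame(y), response_label), X)
  sds <- vapply(M, stats::sd, 0)
  if (any(sds == 0)) {
    stop("pearson_matrix: constant column '", names(M)[sds == 0][1],
         "' has undefined correlation", call. = FALSE)
  }
  n <- length(ids)
  r <- stats::cor(M)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- 0
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[p < 0.05] <- "*"
  stars[p < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(labels = colnames(r), r = r, p = p, stars = stars, n = n),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                        ifelse(x$stars == "", "", paste0(" ", x$stars))),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[upper.tri(disp)] <- ""
  cat("Pearson correlations (n =", x$n, "):\n")
  print(noquote(disp))
  cat("*: p < 0.05, **: p < 0.01 (two-tailed)\n")
  invisible(x)
}

#' Collinearity filter on a descriptor pool
#'
#' Enforces the model-building rule that all pairwise correlations among
#' retained descriptors satisfy |r| < `threshold`. While any descriptor pair
#' violates the rule, the pair with the largest |r| is resolved by dropping
#' whichever member is less correlated (in absolute value) with the response.
#'
#' @param cm a `correlation_matrix` from [pearson_matrix()] with the response
#'   as its first label.
#' @param threshold pairwise |r| bound, default 0.5.
#' @return list with `selected` (descriptor names retained, original order)
#'   and `dropped_for_collinearity` (data frame of dropped name, partner, r).
#' @export
collinearity_filter <- function(cm, threshold = 0.5) {
  stopifnot(inherits(cm, "correlation_matrix"))
  resp <- cm$labels[1]
  keep <- cm$labels[-1]
  dropped <- data.frame(dropped = character(0), partner = character(0),
                        r = numeric(0))
  repeat {
    if (length(keep) < 2) break
    R <- abs(cm$r[keep, keep, drop = FALSE])
    diag(R) <- 0
    if (max(R) < threshold) break
    ij <- which(R == max(R), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    vs_resp <- abs(cm$r[resp, pair])
    # drop the member weaker against the response; lexicographic tie-break
    loser <- pair[order(vs_resp, rank(pair))][1]
    winner <- setdiff(pair, loser)
    dropped <- rbind(dropped,
                     data.frame(dropped = loser, partner = winner,
                                r = cm$r[pair[1], pair[2]]))
    keep <- setdiff(keep, loser)
  }
  list(selected = keep, dropped_for_collinearity = dropped)
}

#' Stepwise multiple linear regression descriptor selection
#'
#' Classical forward-entry / backward-removal stepwise selection on partial
#' F-tests: at each cycle the candidate with the smallest entry p-value below
#' `p_enter` is added, then any included descriptor whose removal p-value
#' exceeds `p_remove` is dropped (largest first). Ties on p are broken by
#' lexicographic name, making the procedure invariant to pool column order.
#' Candidates that would make the design rank-deficient are skipped and
#' logged. Terminates when no entry or removal changes the model.
#'
#' @param pool data frame (or matrix) of candidate descriptor columns.
#' @param response numeric response vector, same length as `nrow(pool)`.
#' @param p_enter entry threshold on the partial-F p-value, default 0.05.
#' @param p_remove removal threshold, default 0.10; must exceed `p_enter`.
#' @return an object of class `selection_result`: list with `selected`
#'   (names in entry order), `steps` (per-step data frame of action,
#'   variable, F, p) and `skipped` (rank-deficiency log).
#' @export
stepwise_mlr_select <- function(pool, response, p_enter = 0.05,
                                p_remove = 0.10) {
  if (p_enter >= p_remove) {
    stop("stepwise_mlr_select: p_enter must be < p_remove", call. = FALSE)
  }
  dat <- as.data.frame(pool)
  if (nrow(dat) != length(response)) {
    stop("stepwise_mlr_select: pool and response sizes differ", call. = FALSE)
  }
  dat$.y <- as.numeric(response)
  vars <- setdiff(names(dat), ".y")
  selected <- character(0)
  steps <- data.frame(action = character(0), variable = character(0),
                      F = numeric(0), p = numeric(0))
  skipped <- character(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    if (iter > 2 * length(vars) + 10) break  # cycling guard
    changed <- FALSE
    cand <- setdiff(vars, selected)
    if (length(cand)) {
      base_fit <- stats::lm(stats::reformulate(c("1", selected), ".y"),
                            data = dat)
      a <- stats::add1(base_fit, scope = stats::reformulate(c(selected, cand)),
                       test = "F")
      a <- a[rownames(a) %in% cand, , drop = FALSE]
      pv <- a[["Pr(>F)"]]
      bad <- is.na(pv)
      if (any(bad)) skipped <- union(skipped, rownames(a)[bad])
      ok <- which(!bad & pv < p_enter)
      if (length(ok)) {
        best <- ok[order(pv[ok], rownames(a)[ok])][1]
        selected <- c(selected, rownames(a)[best])
        steps <- rbind(steps, data.frame(action = "enter",
                                         variable = rownames(a)[best],
                                         F = a[["F value"]][best],
                                         p = pv[best]))
        changed <- TRUE
      }
    }
    if (length(selected)) {
      fit <- stats::lm(stats::reformulate(selected, ".y"), data = dat)
      d <- stats::drop1(fit, test = "F")
      d <- d[rownames(d) %in% selected, , drop = FALSE]
      pv <- d[["Pr(>F)"]]
      worst <- which(!is.na(pv) & pv > p_remove)
      if (length(worst)) {
        out <- worst[order(-pv[worst], rownames(d)[worst])][1]
        victim <- rownames(d)[out]
        selected <- setdiff(selected, victim)
        steps <- rbind(steps, data.frame(action = "remove", variable = victim,
                                         F = d[["F value"]][out],
                                         p = pv[out]))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(selected = selected, steps = steps, skipped = skipped,
                 p_enter = p_enter, p_remove = p_remove),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Stepwise MLR selection (p_enter =", x$p_enter,
      ", p_remove =", x$p_remove, ")\n")
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "<none>", "\n")
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}
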