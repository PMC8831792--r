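#' Fit the augmented complete block design model on check plots
#'
#' Least-squares fit of the ACBD fixed-effect model on the replicated check
#' plots only, under sum-to-zero constraints. Single-environment scope fits
#' `value ~ block + check`; multi-environment scope fits
#' `value ~ block + check + env + block:env + check:env`. Only checks carry
#' replication, so design effects are estimated from them and later applied
#' to the unreplicated entries.
#'
#' @param table trial table (data frame with `line`, `env`, `block`,
#'   `is_check`, `value`).
#' @param scope `"single"` (one environment) or `"multi"`.
#' @return an `acbd_fit` list: `mu`, per-level effect vectors (`block`,
#'   `check`, and for multi scope `env`, `block_env`, `check_env`),
#'   `sigma2` (residual variance), `scope`.
#' @export
fit_acbd <- function(table, scope = c("single", "multi")) {
  scope <- match.arg(scope)
  stopifnot(all(c("line", "env", "block", "is_check", "value") %in% names(table)))
  if (!any(table$is_check)) stop("design error: no check plots")
  envs <- unique(table$env)
  if (scope == "single" && length(envs) > 1) {
    stop("single-environment scope but table has multiple environments")
  }
  if (scope == "multi" && length(envs) < 2) stop("multi scope needs >= 2 environments")
  chk <- table[table$is_check, , drop = FALSE]
  # every block (and block:env cell) holding entries must also hold checks
  need <- unique(table[, c("env", "block")])
  have <- unique(chk[, c("env", "block")])
  miss <- !paste(need$env, need$block) %in% paste(have$env, have$block)
  if (any(miss)) {
    stop("design error: no checks in block ", paste(
      paste(need$env[miss], need$block[miss], sep = "/"), collapse = ", "))
  }
  chk$blockf <- factor(chk$block)
  chk$checkf <- factor(chk$line)
  chk$envf <- factor(chk$env)
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fml <- if (scope == "single") value ~ blockf + checkf else
    value ~ blockf + checkf + envf + blockf:envf + checkf:envf
  fit <- stats::lm(fml, data = chk)
  dc <- stats::dummy.coef(fit)
  clean <- function(v) {
    v[is.na(v)] <- 0
    stats::setNames(as.numeric(v), names(v))
  }
  out <- list(
    mu = as.numeric(dc[["(Intercept)"]]),
    block = clean(dc[["blockf"]]),
    check = clean(dc[["checkf"]]),
    sigma2 = stats::sigma(fit)^2,
    scope = scope
  )
  if (scope == "multi") {
    out$env <- clean(dc[["envf"]])
    be <- clean(dc[["blockf:envf"]])
    ce <- clean(dc[["checkf:envf"]])
    out$block_env <- be
    out$check_env <- ce
  }
  class(out) <- "acbd_fit"
  out
}

#' Adjust unreplicated entries (and checks) with an ACBD fit
#'
#' Entry plots are corrected by subtracting the estimated block effect
#' (single-environment scope) or the block, environment and
#' block-by-environment effects (multi-environment scope); the grand mean
#' stays in, so adjusted means remain on the raw trait scale. A check's
#' adjusted value is its plot mean after the same correction. Values are not
#' truncated: adjusted emergence can fall below 0% or exceed 100%.
#'
#' @param table trial table covered by `fit`.
#' @param fit an `acbd_fit` from [fit_acbd()].
#' @return data frame `line`, `env` (`"across"` for multi scope), `value`,
#'   `is_check`.
#' @export
adjust_entries <- function(table, fit) {
  stopifnot(inherits(fit, "acbd_fit"))
  bl <- as.character(table$block)
  if (!all(bl %in% names(fit$block))) {
    stop("entry in a block not covered by the fit: ",
         paste(unique(bl[!bl %in% names(fit$block)]), collapse = ", "))
  }
  adj <- table$value - fit$block[bl]
  if (fit$scope == "multi") {
    adj <- adj - fit$env[as.character(table$env)] -
      fit$block_env[paste(bl, table$env, sep = ":")]
  }
  env_lab <- if (fit$scope == "multi") "across" else as.character(table$env[1])
  agg <- stats::aggregate(adj, by = list(line = table$line), FUN = mean)
  chk <- stats::aggregate(table$is_check, by = list(line = table$line), FUN = any)
  data.frame(line = agg$line, env = env_lab, value = agg$x,
             is_check = chk$x[match(agg$line, chk$line)],
             stringsAsFactors = FALSE)
}

#' ACBD adjusted means per environment or across environments
#'
#' Convenience wrapper: `scope = "env"` fits and adjusts each environment
#' separately; `scope = "all"` fits the multi-environment model once and
#' returns one across-environment adjusted mean per line.
#'
#' @param table trial table.
#' @param scope `"env"` or `"all"`.
#' @return data frame `line`, `env`, `value`, `is_check`.
#' @export
acbd_adjust <- function(table, scope = c("env", "all")) {
  scope <- match.arg(scope)
  if (scope == "all" && length(unique(table$env)) > 1) {
    fit <- fit_acbd(table, "multi")
    return(adjust_entries(table, fit))
  }
  out <- lapply(split(table, table$env), function(tt) {
    adjust_entries(tt, fit_acbd(tt, "single"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Adjusted means for a replicated trait
#'
#' For replicated designs (e.g. greenhouse coleoptile length), fits the
#' fixed-effect model `value ~ env + rep %in% env` and reports each line's
#' grand mean plus its mean residual, i.e. values corrected for environment
#' and replicate effects on the raw scale.
#'
#' @param table trial table with non-missing `rep`.
#' @return data frame `line`, `env = "across"`, `value`.
#' @export
adjust_replicated <- function(table) {
  stopifnot(all(c("line", "env", "rep", "value") %in% names(table)))
  keep <- !is.na(table$value)
  if (any(!keep)) {
    dropped <- setdiff(table$line, table$line[keep])
    if (length(dropped)) {
      warning("lines with no observations excluded: ",
              paste(dropped, collapse = ", "))
    }
    table <- table[keep, , drop = FALSE]
  }
  envf <- factor(table$env)
  repf <- factor(paste(table$env, table$rep, sep = ":"))
  fit <- if (nlevels(repf) > 1) {
    stats::lm(table$value ~ envf + repf)
  } else stats::lm(table$value ~ 1)
  res <- stats::residuals(fit)
  agg <- stats::aggregate(res, by = list(line = table$line), FUN = mean)
  data.frame(line = agg$line, env = "across",
             value = unname(mean(table$value) + agg$x),
             stringsAsFactors = FALSE)
}
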