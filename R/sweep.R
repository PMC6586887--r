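# Parameter-space sweeps over (a, b) at fixed c, labelling each grid cell
# with the player whose survival probability is strictly highest.  The
# published maps use step 0.001 and one million Monte Carlo rounds per
# cell; the exact solver makes much coarser steps sufficient for the
# qualitative claims, and even the full grid feasible.

#' Winner-region sweep over marksmanship space
#'
#' Evaluates the survival distribution on the lattice of \code{(a, b)}
#' values with spacing \code{step} satisfying \eqn{a \le b}, at fixed
#' \code{c}, and labels each cell with the player holding the strictly
#' highest survival probability (or \code{"TIE"} when the top two are
#' within \code{tie_tol}).  Cells violating the ordering \eqn{b \le c}
#' (possible when \code{c < 1}) are skipped with a warning.
#'
#' @param strategy strategy for player A; see [truel()].
#' @param c marksmanship of player C, fixed across the sweep (default 1,
#'   as in the published maps).
#' @param step lattice spacing in \eqn{(0, 1]}.  The published resolution
#'   is 0.001; the default 0.02 reproduces every qualitative claim in
#'   seconds.
#' @param method \code{"exact"} (Markov-chain solver) or
#'   \code{"monte_carlo"}.
#' @param n games per cell for \code{method = "monte_carlo"}.
#' @param seed simulation seed (\code{monte_carlo} only); drawn and
#'   recorded if \code{NULL}.
#' @param tie_tol margin below which the two best probabilities are
#'   declared tied.  Defaults to 1e-12 for \code{"exact"} and 0 for
#'   \code{"monte_carlo"}.
#' @param switch_prob passed to [truel()] for
#'   \code{"switch_suicide_air"}.
#' @return A data frame of class \code{"truel_sweep"} with columns
#'   \code{a, b, c, strategy, method, p_a, p_b, p_c, winner} and
#'   attributes \code{step}, \code{c}, \code{method}, \code{seed},
#'   \code{tie_tol}.
#' @examples
#' g <- truel_sweep("suicide", c = 1, step = 0.1)
#' region_summary(g)   # no cell where A wins
#' @export
truel_sweep <- function(strategy = truel_strategies(), c = 1, step = 0.02,
                        method = c("exact", "monte_carlo"), n = 1e5,
                        seed = NULL, tie_tol = NULL, switch_prob = 0.5) {
  strategy <- match.arg(strategy)
  method <- match.arg(method)
  c_fix <- c
  if (!is.numeric(c_fix) || length(c_fix) != 1L || c_fix <= 0 || c_fix > 1)
    stop("'c' must be a single value in (0, 1]", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 1)
    stop("'step' must be a single value in (0, 1]", call. = FALSE)
  if (is.null(tie_tol)) tie_tol <- if (method == "exact") 1e-12 else 0

  vals <- seq(0, 1, by = step)
  grid <- expand.grid(a = vals, b = vals, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$a <= grid$b + 1e-9, , drop = FALSE]
  bad <- grid$b > c_fix + 1e-9
  if (any(bad)) {
    warning(sprintf("skipping %d cells with b > c = %g (ordering a <= b <= c)",
                    sum(bad), c_fix), call. = FALSE)
    grid <- grid[!bad, , drop = FALSE]
  }
  nc <- nrow(grid)
  if (nc == 0L) stop("empty sweep grid", call. = FALSE)

  if (method == "monte_carlo") {
    if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
    seed <- as.integer(seed)
  }

  pm <- matrix(NA_real_, nc, 3L)
  if (method == "exact") {
    for (i in seq_len(nc)) {
      bv <- min(grid$b[i], c_fix)          # absorb seq() rounding noise
      x <- truel(min(grid$a[i], bv), bv, c_fix,
                 strategy = strategy, switch_prob = switch_prob)
      pm[i, ] <- exact_survival(x)
    }
  } else {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(if (has_seed) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    for (i in seq_len(nc)) {
      bv <- min(grid$b[i], c_fix)
      x <- truel(min(grid$a[i], bv), bv, c_fix,
                 strategy = strategy, switch_prob = switch_prob)
      eng <- .sim_engine(unname(x$marksmanship), x$strategy, x$switch_prob,
                         as.integer(n), 1e6)
      pm[i, ] <- tabulate(eng$winner, nbins = 3L) / n
    }
  }

  top <- max.col(pm, ties.method = "first")
  second <- apply(pm, 1L, function(p) sort(p, decreasing = TRUE)[2L])
  margin <- pm[cbind(seq_len(nc), top)] - second
  winner <- ifelse(margin > tie_tol, .PLAYERS[top], "TIE")

  out <- data.frame(a = grid$a, b = grid$b, c = c_fix,
                    strategy = strategy, method = method,
                    p_a = pm[, 1L], p_b = pm[, 2L], p_c = pm[, 3L],
                    winner = winner, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, class = c("truel_sweep", "data.frame"),
            step = step, c = c_fix, method = method,
            seed = if (method == "monte_carlo") seed else NA_integer_,
            tie_tol = tie_tol)
}

#' Tally winner regions of a sweep
#'
#' @param grid a [truel_sweep()] result.
#' @return An object of class \code{"truel_region_summary"}: cell counts
#'   per winner (\code{cells_a}, \code{cells_b}, \code{cells_c},
#'   \code{cells_tie}), the total, and the corresponding fractions.
#' @examples
#' region_summary(truel_sweep("abstain", step = 0.1))
#' @export
region_summary <- function(grid) {
  stopifnot(inherits(grid, "truel_sweep"))
  if (nrow(grid) == 0L) stop("empty winner grid", call. = FALSE)
  cnt <- function(lbl) sum(grid$winner == lbl)
  total <- nrow(grid)
  counts <- c(cells_a = cnt("A"), cells_b = cnt("B"),
              cells_c = cnt("C"), cells_tie = cnt("TIE"))
  structure(
    list(strategy = grid$strategy[1L], c = attr(grid, "c"),
         step = attr(grid, "step"), method = grid$method[1L],
         cells_total = total,
         cells_a = counts[["cells_a"]], cells_b = counts[["cells_b"]],
         cells_c = counts[["cells_c"]], cells_tie = counts[["cells_tie"]],
         fractions = counts / total),
    class = "truel_region_summary"
  )
}

#' @export
print.truel_region_summary <- function(x, ...) {
  cat(sprintf("Winner regions: strategy %s, c = %g, step = %g, method %s\n",
              x$strategy, x$c, x$step, x$method))
  cat(sprintf("  %d cells: A %d (%.1f%%), B %d (%.1f%%), C %d (%.1f%%), ties %d\n",
              x$cells_total,
              x$cells_a, 100 * x$fractions[["cells_a"]],
              x$cells_b, 100 * x$fractions[["cells_b"]],
              x$cells_c, 100 * x$fractions[["cells_c"]],
              x$cells_tie))
  invisible(x)
}

#' Compare winner regions of two strategies
#'
#' Both sweeps must share the same grid geometry (same \code{c}, same
#' \code{step}, same cells), so region areas are directly comparable —
#' e.g. abstention versus strongest-opponent targeting, where abstention
#' dramatically enlarges A's region.
#'
#' @param grid1,grid2 [truel_sweep()] results on identical grids.
#' @return A list of two [region_summary()] objects (classes
#'   \code{"truel_region_comparison"}), in argument order.
#' @examples
#' g1 <- truel_sweep("strongest", step = 0.1)
#' g2 <- truel_sweep("abstain", step = 0.1)
#' compare_regions(g1, g2)
#' @export
compare_regions <- function(grid1, grid2) {
  stopifnot(inherits(grid1, "truel_sweep"), inherits(grid2, "truel_sweep"))
  same <- isTRUE(all.equal(attr(grid1, "step"), attr(grid2, "step"))) &&
    isTRUE(all.equal(attr(grid1, "c"), attr(grid2, "c"))) &&
    nrow(grid1) == nrow(grid2) &&
    isTRUE(all.equal(grid1$a, grid2$a)) &&
    isTRUE(all.equal(grid1$b, grid2$b))
  if (!same)
    stop("sweep grids have mismatched geometry (c, step or cells differ)",
         call. = FALSE)
  structure(list(first = region_summary(grid1), second = region_summary(grid2)),
            class = "truel_region_comparison")
}

#' @export
print.truel_region_comparison <- function(x, ...) {
  print(x$first)
  print(x$second)
  invisible(x)
}

#' Write / read a sweep as CSV
#'
#' One record per grid cell with header
#' \code{a,b,c,strategy,method,p_a,p_b,p_c,winner}; probabilities are
#' printed with 12 significant digits.
#'
#' @param grid a [truel_sweep()] result.
#' @param path file path.
#' @return \code{write_sweep_csv} returns \code{path} invisibly;
#'   \code{read_sweep_csv} returns a \code{"truel_sweep"} data frame
#'   (grid attributes are reconstructed from the records).
#' @export
write_sweep_csv <- function(grid, path) {
  stopifnot(inherits(grid, "truel_sweep"))
  fmt <- function(v) vapply(v, function(z) sprintf("%.12g", z), character(1L))
  df <- data.frame(a = fmt(grid$a), b = fmt(grid$b), c = fmt(grid$c),
                   strategy = grid$strategy, method = grid$method,
                   p_a = fmt(grid$p_a), p_b = fmt(grid$p_b),
                   p_c = fmt(grid$p_c), winner = grid$winner,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sweep_csv
#' @export
read_sweep_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("a", "b", "c", "strategy", "method", "p_a", "p_b", "p_c", "winner")
  if (!all(need %in% names(df)))
    stop("not a sweep CSV: missing columns", call. = FALSE)
  ua <- sort(unique(df$a))
  step <- if (length(ua) > 1L) min(diff(ua)) else NA_real_
  structure(df[need], class = c("truel_sweep", "data.frame"),
            step = step, c = df$c[1L], method = df$method[1L],
            seed = NA_integer_,
            tie_tol = NA_real_)
}

#' Plot winner regions
#'
#' Base-graphics map of the winner label over the \code{(a, b)} triangle
#' \eqn{a \le b}, one coloured tile per grid cell.
#'
#' @param x a [truel_sweep()] result.
#' @param col colours for A, B, C and TIE cells.
#' @param ... passed to [graphics::image()].
#' @return \code{x}, invisibly.
#' @export
plot.truel_sweep <- function(x, col = c(A = "#d95f02", B = "#1b9e77",
                                        C = "#7570b3", TIE = "grey70"), ...) {
  av <- sort(unique(x$a))
  bv <- sort(unique(x$b))
  z <- matrix(NA_integer_, length(av), length(bv))
  code <- match(x$winner, names(col))
  z[cbind(match(x$a, av), match(x$b, bv))] <- code
  graphics::image(av, bv, z, col = col, zlim = c(1L, length(col)),
                  xlab = "a (marksmanship of A)", ylab = "b (marksmanship of B)",
                  main = sprintf("Winner regions: %s, c = %g",
                                 x$strategy[1L], attr(x, "c")), ...)
  present <- sort(unique(code))
  graphics::legend("bottomright", legend = names(col)[present],
                   fill = col[present], bg = "white")
  invisible(x)
}
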