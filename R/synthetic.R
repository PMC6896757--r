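#' Specification for a planted-theme pile-sort simulator
#'
#' The real pile-sort data behind the method (nine sorters, 49 quotes, 3-12
#' piles each) are not publicly deposited, so the package validates itself
#' on simulated studies with known ("planted") theme structure. Quotes are
#' assigned round-robin to `n_themes` latent themes; each sorter starts from
#' one pile per theme and then deviates: adjacent theme pairs are lumped
#' into one pile with probability `p_merge`, a theme is split into two piles
#' with probability `p_split`, and each quote is misfiled into a uniformly
#' random *other* pile of that sorter with probability `noise`.
#'
#' Defaults state the scale of the motivating study: 49 quotes, 6 latent
#' themes (the number of groups its network analysis produced), 9 sorters,
#' and merge/split rates of 0.2 which make the realised pile counts range
#' over roughly 3-12. The default `noise` of 0.1 represents mild sorter
#' idiosyncrasy; set it to 0 for the clean planted-clique limit.
#'
#' @param n_quotes number of quotes N.
#' @param n_themes number of latent themes K (K <= N).
#' @param n_sorters number of sorters S.
#' @param noise per-(sorter, quote) misfiling probability in `[0, 1]`.
#' @param p_merge probability, per adjacent theme pair, that a sorter lumps
#'   the two themes into one pile.
#' @param p_split probability, per theme, that a sorter splits it into two
#'   piles.
#' @param seed integer root seed; per-sorter sub-streams are derived from it
#'   so adding a sorter does not perturb the others.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_quotes = 49L, n_themes = 6L, n_sorters = 9L,
                           noise = 0.1, p_merge = 0.2, p_split = 0.2,
                           seed = 1L) {
  if (n_themes > n_quotes)
    pte_stop_input("n_themes must not exceed n_quotes")
  if (n_quotes < 2L || n_themes < 1L || n_sorters < 1L)
    pte_stop_input("need n_quotes >= 2, n_themes >= 1, n_sorters >= 1")
  for (p in c(noise, p_merge, p_split))
    if (p < 0 || p > 1) pte_stop_input("probabilities must lie in [0, 1]")
  structure(list(n_quotes = as.integer(n_quotes),
                 n_themes = as.integer(n_themes),
                 n_sorters = as.integer(n_sorters),
                 noise = noise, p_merge = p_merge, p_split = p_split,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> N = ", x$n_quotes, ", K = ", x$n_themes,
      ", S = ", x$n_sorters, ", noise = ", x$noise,
      ", p_merge = ", x$p_merge, ", p_split = ", x$p_split,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# deterministic per-sorter sub-seed; stays below 2^31 - 1
sorter_seed <- function(seed, s) {
  ((as.numeric(seed) %% 1000003) * 1009 + s * 7919) %% 2147483647
}

#' Generate a pile-sort study with planted themes
#'
#' Runs the generative model described in [synthetic_spec()]. The RNG state
#' is restored on exit; all randomness flows from the spec's seed, and each
#' sorter consumes an independent sub-stream.
#'
#' @param spec a [synthetic_spec()].
#' @return An object of class `synthetic_study`: list with `study` (a
#'   [sorting_study()]), `planted` (named vector quote -> true theme label,
#'   exactly K groups) and `spec`.
#' @examples
#' sim <- generate_pilesort(synthetic_spec(n_quotes = 12, n_themes = 3,
#'                                         n_sorters = 4, noise = 0,
#'                                         p_merge = 0, p_split = 0))
#' summary(sim$study)   # every sorter has exactly 3 piles
#' @export
generate_pilesort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  N <- spec$n_quotes; K <- spec$n_themes; S <- spec$n_sorters
  width <- max(2L, nchar(as.character(N)))
  qid <- sprintf(paste0("q%0", width, "d"), seq_len(N))
  theme <- ((seq_len(N) - 1L) %% K) + 1L
  planted <- stats::setNames(paste0("T", theme), qid)

  recs <- vector("list", S)
  for (s in seq_len(S)) {
    set.seed(sorter_seed(spec$seed, s))
    # adjacent-theme merges: themes t and t+1 fall in one merge group
    merged <- cumsum(c(1L, as.integer(stats::runif(max(K - 1L, 0L)) >= spec$p_merge)))
    split_theme <- stats::runif(K) < spec$p_split
    designated <- character(N)
    for (i in seq_len(N)) {
      t <- theme[i]
      if (split_theme[t]) {
        designated[i] <- paste0("t", t, sample(c("a", "b"), 1L))
      } else {
        designated[i] <- paste0("p", merged[t])
      }
    }
    piles <- sort(unique(designated))
    final <- designated
    if (length(piles) > 1L && spec$noise > 0) {
      for (i in seq_len(N)) {
        if (stats::runif(1L) < spec$noise) {
          others <- setdiff(piles, designated[i])
          final[i] <- others[sample.int(length(others), 1L)]
        }
      }
    }
    recs[[s]] <- data.frame(sorter_id = sprintf("s%02d", s), quote_id = qid,
                            pile = final, stringsAsFactors = FALSE)
  }
  study <- sorting_study(do.call(rbind, recs), quotes = qid)
  structure(list(study = study, planted = canonical_labels(planted),
                 spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", x$spec$n_quotes, " quotes, ",
      x$spec$n_themes, " planted themes, ", x$spec$n_sorters,
      " sorters (noise = ", x$spec$noise, ")\n", sep = "")
  invisible(x)
}

#' Theme-recovery experiment on simulated studies
#'
#' Generates `replicates` independent studies from `spec` (shifting the seed
#' per replicate), runs the chosen community-detection algorithm on each
#' co-occurrence network, and scores the best-Q partition against the
#' planted themes with the adjusted Rand index.
#'
#' @param spec a [synthetic_spec()].
#' @param algorithm `"greedy_modularity"` or `"girvan_newman"`.
#' @param replicates number of independent studies.
#' @return A `recovery_summary`: list with `mean`, `sd`, `ari` (per
#'   replicate), `algorithm`, `spec`.
#' @export
recovery_experiment <- function(spec, algorithm = c("greedy_modularity",
                                                    "girvan_newman"),
                                replicates = 30L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  algorithm <- match.arg(algorithm)
  fn <- switch(algorithm, greedy_modularity = greedy_modularity,
               girvan_newman = girvan_newman)
  ari <- vapply(seq_len(replicates), function(r) {
    sp <- spec
    sp$seed <- as.integer((spec$seed + 104729 * (r - 1)) %% 2147483647)
    sim <- generate_pilesort(sp)
    net <- build_network(sim$study)
    adjusted_rand(best_partition(fn(net)), sim$planted)
  }, numeric(1L))
  structure(list(mean = mean(ari), sd = stats::sd(ari), ari = ari,
                 algorithm = algorithm, spec = spec,
                 replicates = as.integer(replicates)),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Theme recovery (", x$algorithm, ", ", x$replicates,
      " replicates): mean ARI = ", sprintf("%.3f", x$mean),
      " (sd ", sprintf("%.3f", x$sd), ")\n", sep = "")
  invisible(x)
}
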