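#' Configuration for the resource-prey-predator agent-based model
#'
#' A grid-world energy ABM: prey graze a regrowing basal resource, predators
#' consume co-located prey in their diet, all agents pay a metabolic cost per
#' step, die at zero energy and reproduce by fission above an energy
#' threshold. Specialist predators have a single prey species in their diet;
#' generalists have several. The optional preference matrix (second model
#' variant) weights a generalist's choice among co-located prey.
#'
#' Diets are assigned deterministically: specialist predator `i` eats prey
#' `i`; generalist `j` eats `generalist_diet_size` evenly spaced prey species
#' offset by `j`, so diets overlap and intra-guild competition is planted.
#'
#' @param n_prey,n_predators Numbers of prey and predator species (defaults
#'   17 and 8).
#' @param n_specialists How many predators are specialists (singleton diet).
#' @param generalist_diet_size Diet breadth of generalist predators.
#' @param grid_side Side of the square toroidal grid.
#' @param resource_regrowth Resource units added per cell per step.
#' @param resource_max Resource carrying capacity per cell.
#' @param init_prey,init_predators Initial individuals per species.
#' @param prey_gain Energy a prey gains per unit resource consumed.
#' @param predator_gain Energy a predator gains per prey consumed; an
#'   optional jack-of-all-trades penalty scales it by
#'   `1 / d^diet_tradeoff` for a diet of `d` prey species.
#' @param diet_tradeoff Exponent of the diet-breadth gain penalty
#'   (default 0: none; satiation already equalizes realized intake across
#'   diet breadths).
#' @param prey_K Intraspecific interference scale: a prey individual's
#'   grazing gain is divided by `1 + N_s / prey_K` where `N_s` is its
#'   species' population, a Beverton-Holt self-limitation that lets the 17
#'   prey species coexist on the shared resource instead of excluding one
#'   another.
#' @param env_phi,env_sd AR(1) persistence and innovation SD of each prey
#'   species' log environmental suitability, which multiplies its grazing
#'   gain. This plants slow, species-specific abundance fluctuations that
#'   predators can track; set `env_sd = 0` for a constant environment.
#' @param prey_cost,predator_cost Metabolic cost per step.
#' @param prey_repro Prey energy threshold for fission (deterministic).
#' @param predator_repro Predator energy threshold above which reproduction
#'   becomes possible.
#' @param predator_repro_prob Per-step probability that a predator above the
#'   threshold reproduces; caps predator population growth rate so that
#'   predators track rather than overrun their prey.
#' @param predator_mortality Per-step background death probability of
#'   predators (senescence/disease), setting their demographic turnover
#'   time.
#' @param predator_K Intraspecific interference scale for predators: a
#'   hungry predator hunts with probability `1 / (1 + P_s / predator_K)`
#'   where `P_s` is its species' population (territoriality), which keeps
#'   predators a perturbation on prey dynamics rather than the dominant
#'   control.
#' @param satiation Predators hunt only while their energy is below this
#'   ceiling (default the reproduction threshold), a standard satiation rule
#'   that keeps consumption tied to demand.
#' @param preference Optional `n_predators x n_prey` preference matrix; rows
#'   are renormalized over each predator's diet. `NULL` for the unweighted
#'   variant.
#' @param immigration Expected immigrants per species per step (Poisson), a
#'   small open-system flux that allows recolonization after local
#'   extinction, as expected for an open marine community.
#' @param steps,burn_in Census length and discarded transient.
#' @param max_agents Abort threshold against population explosion.
#' @param seed Integer seed; simulations are reproducible given it.
#' @return An `abm_config` list.
#' @export
abm_config <- function(n_prey = 17, n_predators = 8, n_specialists = 4,
                       generalist_diet_size = 5, grid_side = 24,
                       resource_regrowth = 0.5, resource_max = 4,
                       init_prey = 60, init_predators = 20,
                       prey_gain = 4, predator_gain = 25,
                       diet_tradeoff = 0, prey_K = 80,
                       env_phi = 0.97, env_sd = 0.15,
                       prey_cost = 1, predator_cost = 0.2,
                       prey_repro = 10, predator_repro = 12,
                       predator_repro_prob = 0.25,
                       predator_mortality = 0.06, predator_K = 80,
                       satiation = 2.5 * predator_repro, immigration = 0.05,
                       preference = NULL,
                       steps = 600, burn_in = 100,
                       max_agents = 50000, seed = 1) {
  stopifnot(n_prey >= 1, n_predators >= 0, n_specialists <= n_predators,
            generalist_diet_size >= 1, generalist_diet_size <= n_prey,
            burn_in < steps)
  diets <- vector("list", n_predators)
  if (n_predators > 0) {
    for (s in seq_len(n_predators)) {
      if (s <= n_specialists) {
        diets[[s]] <- ((s - 1) %% n_prey) + 1
      } else {
        stride <- max(1, n_prey %/% generalist_diet_size)
        diets[[s]] <- sort(unique(((s - 1) + stride *
                                     (0:(generalist_diet_size - 1))) %% n_prey + 1))
      }
    }
  }
  if (!is.null(preference)) {
    preference <- as.matrix(preference)
    if (!all(dim(preference) == c(n_predators, n_prey))) {
      stop("preference must be n_predators x n_prey")
    }
    if (any(preference < 0)) stop("preference weights must be non-negative")
    for (s in seq_len(n_predators)) {
      w <- preference[s, diets[[s]]]
      if (sum(w) <= 0) stop("a predator's diet has zero total preference")
      preference[s, ] <- 0
      preference[s, diets[[s]]] <- w / sum(w)
    }
  }
  if (any(vapply(diets, length, 1L) == 0) && n_predators > 0) {
    stop("every predator needs a non-empty diet")
  }
  structure(list(
    n_prey = n_prey, n_predators = n_predators,
    n_specialists = n_specialists,
    generalist_diet_size = generalist_diet_size, grid_side = grid_side,
    resource_regrowth = resource_regrowth, resource_max = resource_max,
    init_prey = init_prey, init_predators = init_predators,
    prey_gain = prey_gain, predator_gain = predator_gain,
    diet_tradeoff = diet_tradeoff, prey_K = prey_K,
    env_phi = env_phi, env_sd = env_sd,
    prey_cost = prey_cost, predator_cost = predator_cost,
    prey_repro = prey_repro, predator_repro = predator_repro,
    predator_repro_prob = predator_repro_prob,
    predator_mortality = predator_mortality, predator_K = predator_K,
    satiation = satiation, immigration = immigration,
    preference = preference, diets = diets, steps = steps,
    burn_in = burn_in, max_agents = max_agents, seed = seed
  ), class = "abm_config")
}

#' True interaction labels implied by an ABM configuration
#'
#' Every unordered species pair is labeled exactly once:
#' `specialist` / `generalist` for predator-prey pairs in the diet,
#' `competition` for prey-prey pairs (all prey share the basal resource;
#' pairs sharing a predator additionally experience apparent competition)
#' and for predator-predator pairs sharing at least one prey (intra-guild),
#' `none` otherwise.
#'
#' @param cfg An [abm_config()].
#' @return Data frame `species_a`, `species_b` (indices, a < b), `label`.
#' @export
abm_pair_labels <- function(cfg) {
  S <- cfg$n_prey + cfg$n_predators
  pairs <- utils::combn(S, 2)
  lab <- character(ncol(pairs))
  is_prey <- function(i) i <= cfg$n_prey
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (is_prey(a) && is_prey(b)) {
      lab[k] <- "competition"
    } else if (!is_prey(a) && !is_prey(b)) {
      da <- cfg$diets[[a - cfg$n_prey]]; db <- cfg$diets[[b - cfg$n_prey]]
      lab[k] <- if (length(intersect(da, db)) > 0) "competition" else "none"
    } else {
      prey <- min(a, b); pred <- max(a, b) - cfg$n_prey
      diet <- cfg$diets[[pred]]
      if (prey %in% diet) {
        lab[k] <- if (length(diet) == 1) "specialist" else "generalist"
      } else {
        lab[k] <- "none"
      }
    }
  }
  data.frame(species_a = pairs[1, ], species_b = pairs[2, ], label = lab,
             stringsAsFactors = FALSE)
}

# weighted-without-replacement selection keys (Efraimidis-Spirakis):
# higher key wins; weight 0 never selected
es_keys <- function(w) {
  k <- stats::runif(length(w))^(1 / pmax(w, 1e-12))
  k[w <= 0] <- -1
  k
}

# position of each element within its group when ordered by decreasing
# priority; O(n log n), no per-group apply
rank_within <- function(group, priority) {
  o <- order(group, -priority)
  gs <- group[o]
  pos <- sequence(rle(gs)$lengths)
  out <- integer(length(group))
  out[o] <- pos
  out
}

#' Run the resource-prey-predator ABM
#'
#' Agents random-walk on a toroidal grid; prey split the local resource
#' evenly, predators consume at most one co-located diet prey per step
#' (chosen with probability proportional to preference times local
#' availability in the weighted variant); energy bookkeeping drives death
#' and fission reproduction. The per-step census of every species is
#' recorded.
#'
#' @param cfg An [abm_config()].
#' @return An `abm_result` list: `census` (steps x species matrix, prey
#'   first), `labels` (from [abm_pair_labels()]), `births`/`deaths` per
#'   step, and the `config`.
#' @export
run_abm <- function(cfg) {
  set.seed(cfg$seed)
  S <- cfg$n_prey + cfg$n_predators
  L <- cfg$grid_side
  ncell <- L * L

  species <- rep(seq_len(S), times = c(rep(cfg$init_prey, cfg$n_prey),
                                       rep(cfg$init_predators,
                                           cfg$n_predators)))
  n0 <- length(species)
  cell <- sample.int(ncell, n0, replace = TRUE)
  energy <- ifelse(species <= cfg$n_prey, cfg$prey_repro / 2,
                   cfg$predator_repro / 2)
  resource <- matrix(cfg$resource_max, L, L)
  env <- numeric(cfg$n_prey)  # log suitability per prey species

  census <- matrix(0L, cfg$steps, S,
                   dimnames = list(NULL, c(sprintf("prey_%02d",
                                                   seq_len(cfg$n_prey)),
                                           sprintf("pred_%02d",
                                                   seq_len(cfg$n_predators)))))
  births <- deaths <- integer(cfg$steps)

  # cell index helpers on the torus
  row_of <- function(cl) ((cl - 1L) %% L)
  col_of <- function(cl) ((cl - 1L) %/% L)
  to_cell <- function(r, cl) cl * L + r + 1L

  for (t in seq_len(cfg$steps)) {
    n <- length(species)
    if (n == 0) {
      census[t:cfg$steps, ] <- 0L
      break
    }
    if (n > cfg$max_agents) {
      stop(sprintf("ABM aborted at step %d: %d agents exceeds max_agents = %d (population explosion)",
                   t, n, cfg$max_agents))
    }
    # 1. random walk to a von Neumann neighbour
    dir <- sample.int(4L, n, replace = TRUE)
    r <- row_of(cell); cl <- col_of(cell)
    r <- (r + c(1L, -1L, 0L, 0L)[dir]) %% L
    cl <- (cl + c(0L, 0L, 1L, -1L)[dir]) %% L
    cell <- to_cell(r, cl)

    is_prey <- species <= cfg$n_prey
    # slow environmental suitability fluctuation per prey species
    env <- cfg$env_phi * env + stats::rnorm(cfg$n_prey, 0, cfg$env_sd)
    # 2. prey graze: local resource split evenly, capped at 1 unit each
    if (any(is_prey)) {
      pc <- cell[is_prey]
      n_at <- tabulate(pc, ncell)
      supply <- pmin(resource[seq_len(ncell)], n_at)
      share <- numeric(ncell)
      pos <- n_at > 0
      share[pos] <- supply[pos] / n_at[pos]
      pops <- tabulate(species, S)
      suit <- exp(env)[species[is_prey]] /
        (1 + pops[species[is_prey]] / cfg$prey_K)
      energy[is_prey] <- energy[is_prey] +
        cfg$prey_gain * suit * share[pc]
      resource[seq_len(ncell)] <- resource[seq_len(ncell)] - supply
    }
    resource <- pmin(resource + cfg$resource_regrowth, cfg$resource_max)

    # 3. predation, one species at a time
    eaten <- logical(length(species))
    if (cfg$n_predators > 0) {
      for (s in seq_len(cfg$n_predators)) {
        sp <- cfg$n_prey + s
        pidx <- which(species == sp & energy < cfg$satiation)
        if (length(pidx) > 0) {
          hunt_p <- 1 / (1 + length(which(species == sp)) / cfg$predator_K)
          pidx <- pidx[stats::runif(length(pidx)) < hunt_p]
        }
        if (length(pidx) == 0) next
        diet <- cfg$diets[[s]]
        gain_s <- cfg$predator_gain / length(diet)^cfg$diet_tradeoff
        if (is.null(cfg$preference)) {
          # unweighted variant: any co-located diet prey can be taken
          cand <- which(is_prey & !eaten & species %in% diet)
          if (length(cand) == 0) next
          avail <- tabulate(cell[cand], ncell)
          pcell <- cell[pidx]
          kills <- pmin(tabulate(pcell, ncell), avail)
          if (all(kills == 0)) next
          # predators that succeed: random rank within cell, up to the
          # local prey count
          ord <- rank_within(pcell, stats::runif(length(pidx)))
          fed <- ord <= kills[pcell]
          energy[pidx[fed]] <- energy[pidx[fed]] + gain_s
          vord <- rank_within(cell[cand], stats::runif(length(cand)))
          eaten[cand[vord <= kills[cell[cand]]]] <- TRUE
        } else {
          # preference-weighted variant: each predator forms a search
          # image for one diet species (drawn by preference) and succeeds
          # only if that species is locally present
          w <- cfg$preference[s, diet]
          target <- diet[1 + findInterval(stats::runif(length(pidx)),
                                          cumsum(w) / sum(w))]
          for (k in diet) {
            tk <- which(target == k)
            if (length(tk) == 0) next
            cand <- which(is_prey & !eaten & species == k)
            if (length(cand) == 0) next
            avail <- tabulate(cell[cand], ncell)
            pcell <- cell[pidx[tk]]
            kills <- pmin(tabulate(pcell, ncell), avail)
            if (all(kills == 0)) next
            ord <- rank_within(pcell, stats::runif(length(tk)))
            fed <- ord <= kills[pcell]
            energy[pidx[tk][fed]] <- energy[pidx[tk][fed]] + gain_s
            vord <- rank_within(cell[cand], stats::runif(length(cand)))
            eaten[cand[vord <= kills[cell[cand]]]] <- TRUE
          }
        }
      }
    }

    # 4. metabolism, starvation, background predator mortality
    energy <- energy - ifelse(is_prey, cfg$prey_cost, cfg$predator_cost)
    dead <- eaten | energy <= 0
    dead[!is_prey] <- dead[!is_prey] |
      stats::runif(sum(!is_prey)) < cfg$predator_mortality
    deaths[t] <- sum(dead)
    if (any(dead)) {
      keep <- !dead
      species <- species[keep]; cell <- cell[keep]; energy <- energy[keep]
      is_prey <- is_prey[keep]
    }

    # 5. fission reproduction: prey at threshold, predators above
    # threshold with fixed per-step probability
    thr <- ifelse(is_prey, cfg$prey_repro, cfg$predator_repro)
    can <- energy >= thr
    can[!is_prey] <- can[!is_prey] &
      stats::runif(sum(!is_prey)) < cfg$predator_repro_prob
    rep_idx <- which(can)
    births[t] <- length(rep_idx)
    if (length(rep_idx) > 0) {
      energy[rep_idx] <- energy[rep_idx] / 2
      species <- c(species, species[rep_idx])
      cell <- c(cell, cell[rep_idx])
      energy <- c(energy, energy[rep_idx])
    }

    # 6. immigration from the open system
    if (cfg$immigration > 0) {
      n_imm <- stats::rpois(S, cfg$immigration)
      if (sum(n_imm) > 0) {
        imm_sp <- rep(seq_len(S), n_imm)
        species <- c(species, imm_sp)
        cell <- c(cell, sample.int(ncell, length(imm_sp), replace = TRUE))
        energy <- c(energy, ifelse(imm_sp <= cfg$n_prey,
                                   cfg$prey_repro / 2,
                                   cfg$predator_repro / 2))
        births[t] <- births[t] + length(imm_sp)
      }
    }
    census[t, ] <- tabulate(species, S)
  }

  structure(list(census = census, labels = abm_pair_labels(cfg),
                 births = births, deaths = deaths, config = cfg),
            class = "abm_result")
}

#' @export
print.abm_result <- function(x, ...) {
  last <- x$census[nrow(x$census), ]
  cat(sprintf("abm_result: %d steps, %d prey + %d predator species, final population %d\n",
              nrow(x$census), x$config$n_prey, x$config$n_predators,
              sum(last)))
  invisible(x)
}

#' Labeled abundance correlations from an ABM run
#'
#' Pearson correlations between every species pair's post-burn-in census
#' series, tagged with the pair's true interaction label. Pairs containing a
#' constant (e.g. extinct-from-burn-in) series have no defined correlation
#' and are dropped.
#'
#' @param res An [run_abm()] result.
#' @param burn_in Steps to discard (defaults to the config's).
#' @param stride Keep every `stride`-th census to thin serial dependence.
#' @return Data frame `species_a`, `species_b`, `label`, `r`; attribute
#'   `dropped` counts undefined pairs.
#' @export
abm_correlations <- function(res, burn_in = res$config$burn_in, stride = 1) {
  if (burn_in >= nrow(res$census)) stop("burn_in must be < steps")
  X <- res$census[seq(burn_in + 1, nrow(res$census), by = stride), ,
                  drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  lab <- res$labels
  ok <- sds[lab$species_a] > 0 & sds[lab$species_b] > 0
  R <- suppressWarnings(stats::cor(X))
  out <- lab[ok, , drop = FALSE]
  out$r <- R[cbind(out$species_a, out$species_b)]
  attr(out, "dropped") <- sum(!ok)
  rownames(out) <- NULL
  out
}

#' Run a corpus of ABM simulations with preservation-degraded copies
#'
#' For each run the perfect-preservation census is stored together with
#' `n_degradations` thinned copies: each species is independently assigned
#' one of the preservation categories and its census series is binomially
#' thinned with the category's probability, mirroring trait-dependent
#' taphonomic loss. The corpus calibrates the preservation-bias coefficient.
#'
#' @param n_runs Number of base simulations.
#' @param n_degradations Degraded copies per run.
#' @param degradation_probs Preservation probabilities of the three
#'   categories: either a fixed numeric vector, or a function drawing one
#'   vector per case. The default draws category 1 perfect, category 2
#'   mildly thinned and category 3 anywhere from mildly to severely
#'   thinned, so corpus cases span a gradient from near-perfect to heavily
#'   biased preservation.
#' @param cfg_sampler Function `(seed) -> abm_config` drawing initial
#'   conditions; the default jitters initial populations and resource
#'   regrowth uniformly around the standard configuration.
#' @param seed Master seed.
#' @param steps,burn_in Passed to the default sampler's configs.
#' @return An `abm_corpus` list of runs; each run holds `census` (post
#'   burn-in), `labels`, and a list of degradations with `census` and
#'   per-species `category`.
#' @export
run_abm_corpus <- function(n_runs = 50, n_degradations = 4,
                           degradation_probs = default_degradation_probs,
                           cfg_sampler = NULL, seed = 1,
                           steps = 260, burn_in = 60) {
  stopifnot(n_runs >= 1, n_degradations >= 1)
  if (!is.function(degradation_probs)) {
    if (any(degradation_probs <= 0 | degradation_probs > 1)) {
      stop("degradation_probs must lie in (0, 1]")
    }
    probs_fixed <- degradation_probs
    degradation_probs <- function() probs_fixed
  }
  if (is.null(cfg_sampler)) {
    cfg_sampler <- function(s) {
      set.seed(s)
      abm_config(init_prey = sample(18:35, 1),
                 init_predators = sample(6:14, 1),
                 resource_regrowth = stats::runif(1, 0.2, 0.3),
                 steps = steps, burn_in = burn_in, seed = s)
    }
  }
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- cfg_sampler(run_seeds[i])
    res <- run_abm(cfg)
    X <- res$census[seq(cfg$burn_in + 1, cfg$steps), , drop = FALSE]
    S <- ncol(X)
    degs <- vector("list", n_degradations)
    set.seed(run_seeds[i] + 1)
    for (d in seq_len(n_degradations)) {
      case_probs <- degradation_probs()
      # category shares also vary per case, so corpus cases span the
      # whole range from barely to almost entirely degraded communities
      wts <- stats::rexp(length(case_probs))
      cat_idx <- sample.int(length(case_probs), S, replace = TRUE,
                            prob = wts / sum(wts))
      p <- case_probs[cat_idx]
      Xd <- X
      for (j in seq_len(S)) {
        if (p[j] < 1) Xd[, j] <- stats::rbinom(nrow(X), X[, j], p[j])
      }
      degs[[d]] <- list(census = Xd,
                        category = stats::setNames(cat_idx, colnames(X)),
                        probs = stats::setNames(p, colnames(X)))
    }
    runs[[i]] <- list(census = X, labels = res$labels, degradations = degs,
                      config = cfg)
  }
  structure(list(runs = runs, seed = seed), class = "abm_corpus")
}

#' Default per-case preservation-category probabilities
#'
#' Category 1 preserves perfectly; category 2 is mildly thinned; category 3
#' ranges from mild to severe. Drawn once per degradation case.
#'
#' @return Numeric vector of three probabilities.
#' @export
default_degradation_probs <- function() {
  u <- stats::runif(1)
  if (u < 0.15) return(c(1, 1, 1))              # perfect preservation
  if (u < 0.40) return(c(1, stats::runif(1, 0.5, 1), 0.001))  # catastrophic
  c(1, stats::runif(1, 0.1, 1), stats::runif(1, 0.002, 0.3))
}

#' Pool labeled correlations over an ABM corpus
#'
#' @param corpus An [run_abm_corpus()] result.
#' @param stride Census thinning passed through to the correlation step.
#' @return Data frame of labeled correlations pooled over the corpus' base
#'   (perfect-preservation) runs.
#' @export
corpus_correlations <- function(corpus, stride = 1) {
  out <- lapply(corpus$runs, function(run) {
    X <- run$census[seq(1, nrow(run$census), by = stride), , drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    lab <- run$labels
    ok <- sds[lab$species_a] > 0 & sds[lab$species_b] > 0
    R <- suppressWarnings(stats::cor(X))
    lab <- lab[ok, , drop = FALSE]
    lab$r <- R[cbind(lab$species_a, lab$species_b)]
    lab
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
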