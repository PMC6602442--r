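# The iterative pool-based conformational search: a pool of 48 structures
# seeded by rebuilding ULRs, five cycles of 480 operator trials with
# restrained relaxation, energy-based pool replacement under a widening
# structural-diversity radius, and restraint-free final scoring of all
# generated structures.

closeness_radius_at <- function(cycle, config) {
  if (config$cycles <= 1L) return(config$closeness_end)
  f <- (cycle - 1) / (config$cycles - 1)
  config$closeness_start + f * (config$closeness_end - config$closeness_start)
}

#' Initialize the structure pool
#'
#' Generates `config$capacity` members from the input structure by
#' re-building the ULR spans (terminal ULRs freely, interior ULRs through
#' TLC re-closure) with independently seeded torsion draws, followed by a
#' light restrained relaxation. Members that fail to rebuild after 10
#' attempts fall back to a copy of the input.
#'
#' @param input Validated `protein_model`.
#' @param profile A `residue_error_profile` (its `ulrs` drive rebuilding).
#' @param restraints A `restraint_set`.
#' @param config Configuration.
#' @param fraglib Optional `fragment_library` used for torsion draws.
#' @param seed Master seed.
#' @return A `structure_pool`.
#' @export
initialize_pool <- function(input, profile, restraints,
                            config = default_config(), fraglib = NULL,
                            seed = config$seed) {
  members <- vector("list", config$capacity)
  sched <- relax_schedule(config$steps_short, "minimize")
  for (k in seq_len(config$capacity)) {
    mk <- input
    for (u_i in seq_along(profile$ulrs)) {
      u <- profile$ulrs[[u_i]]
      done <- FALSE
      for (att in 1:10) {
        sd <- split_seed(seed, 1000L * k + 20L * u_i + att)
        cand <- with_seed(sd, {
          L <- u[2L] - u[1L] + 1L
          cur <- backbone_torsions_raw(mk)
          if (!is.null(fraglib) && fraglib$window <= L) {
            f <- sample.int(nrow(fraglib$phi), 1L)
            off <- sample.int(L - fraglib$window + 1L, 1L) - 1L
            np <- cur$phi[u[1L]:u[2L]]; ns <- cur$psi[u[1L]:u[2L]]
            np[(off + 1L):(off + fraglib$window)] <- fraglib$phi[f, ]
            ns[(off + 1L):(off + fraglib$window)] <- fraglib$psi[f, ]
          } else {
            np <- wrap180(cur$phi[u[1L]:u[2L]] + stats::rnorm(L, 0, config$mutate_sigma))
            ns <- wrap180(cur$psi[u[1L]:u[2L]] + stats::rnorm(L, 0, config$mutate_sigma))
          }
          apply_span_torsions(mk, u[1L], u[2L], np, ns, config,
                              pick_seed = stats::runif(1L, 1, 1e8))
        })
        if (!is.null(cand) && chain_intact(cand)) { mk <- cand; done <- TRUE; break }
      }
      if (!done) mk <- input   # fall back to the input copy
    }
    mk <- relax(mk, restraints, sched, config)
    en <- evaluate_energy(mk, restraints, config)
    mk$provenance <- "trial"
    members[[k]] <- list(model = mk, energy = en$total_with_restraints,
                         energy_norestr = en$total_without_restraints)
  }
  structure(list(members = members, capacity = config$capacity, cycle = 1L,
                 closeness_radius = closeness_radius_at(1L, config)),
            class = "structure_pool")
}

#' @export
print.structure_pool <- function(x, ...) {
  en <- vapply(x$members, `[[`, numeric(1), "energy")
  cat(sprintf("<structure_pool> %d members, cycle %d, closeness %.2f A, E in [%.2f, %.2f]\n",
              length(x$members), x$cycle, x$closeness_radius, min(en), max(en)))
  invisible(x)
}

# operator weights restricted to operators that can apply to this problem
applicable_weights <- function(model, context) {
  w <- context$weights
  if (!length(rotatable_residues(model))) w["sidechain_perturbation"] <- 0
  if (is.null(context$patch_library) || !length(context$patch_library$patches))
    w["hybridization"] <- 0
  if (!length(context$error_profile$ulrs)) w["loop_modelling"] <- 0
  if (is.null(context$fraglib)) w["fragment_assembly"] <- 0
  if (sum(w) == 0) w["normal_mode"] <- 1
  w / sum(w)
}

#' Generate one cycle of trial structures
#'
#' Applies `config$trials_per_member` seeded operator draws to every pool
#' member (no-op draws re-drawn up to 5 times, then the member is passed
#' through relaxation unmodified), relaxes each trial (short schedule after
#' loop modelling, standard otherwise) and scores it with restraints.
#'
#' @param pool A `structure_pool`.
#' @param context An `operator_context`.
#' @param restraints A `restraint_set`.
#' @param config Configuration.
#' @param seed Cycle seed.
#' @return List of trials: `list(model, energy, energy_norestr, operator)`.
#' @export
generate_trials <- function(pool, context, restraints,
                            config = default_config(), seed = config$seed) {
  trials <- vector("list", length(pool$members) * config$trials_per_member)
  idx <- 0L
  for (m_i in seq_along(pool$members)) {
    base <- pool$members[[m_i]]$model
    w <- applicable_weights(base, context)
    for (t_i in seq_len(config$trials_per_member)) {
      tseed <- split_seed(seed, 31L * m_i + t_i)
      ctx <- context
      ctx$pool <- pool
      op <- NULL; out <- NULL
      for (att in 1:5) {
        ctx$rng_seed <- split_seed(tseed, att)
        op <- with_seed(split_seed(tseed, 90L + att),
                        sample(names(w), 1L, prob = w))
        cand <- apply_operator(op, base, ctx)
        if (!is_noop(cand)) { out <- cand; break }
      }
      if (is.null(out)) { out <- base; op <- "none" }
      steps <- if (identical(op, "loop_modelling")) config$steps_short
      else config$steps_standard
      out <- relax(out, restraints, relax_schedule(steps, "minimize"), config)
      en <- evaluate_energy(out, restraints, config)
      idx <- idx + 1L
      trials[[idx]] <- list(model = out, energy = en$total_with_restraints,
                            energy_norestr = en$total_without_restraints,
                            operator = op, relax_steps = steps)
    }
  }
  trials
}

#' Update the pool with scored trials
#'
#' Trials are processed in ascending restrained energy. Each trial looks
#' for pool members within `closeness_radius` CA-RMSD: if any exist, the
#' highest-energy such member is replaced when the trial's energy is lower;
#' otherwise the pool's overall highest-energy member is replaced when the
#' trial's energy is lower. Pool size is conserved; the closeness radius
#' then advances along its linear schedule (diversity widens with cycles).
#'
#' @param pool A `structure_pool`.
#' @param trials Output of [generate_trials()].
#' @param config Configuration.
#' @return The updated `structure_pool` (fields `accepted` and `cycle`
#'   refreshed).
#' @export
update_pool <- function(pool, trials, config = default_config()) {
  ord <- order(vapply(trials, `[[`, numeric(1), "energy"))
  accepted <- 0L
  pool_ca <- lapply(pool$members, function(m) bb_coords(m$model, "CA"))
  pool_en <- vapply(pool$members, `[[`, numeric(1), "energy")
  for (t_i in ord) {
    tr <- trials[[t_i]]
    tca <- bb_coords(tr$model, "CA")
    rmsds <- vapply(pool_ca, function(P) kabsch_superpose(tca, P)$rmsd,
                    numeric(1))
    close <- which(rmsds <= pool$closeness_radius)
    repl <- if (length(close)) close[which.max(pool_en[close])]
    else which.max(pool_en)
    if (tr$energy < pool_en[repl]) {
      pool$members[[repl]] <- tr
      pool_ca[[repl]] <- tca
      pool_en[repl] <- tr$energy
      accepted <- accepted + 1L
    }
  }
  pool$accepted <- accepted
  pool$cycle <- pool$cycle + 1L
  pool$closeness_radius <- closeness_radius_at(min(pool$cycle, config$cycles),
                                               config)
  pool
}

#' Select and polish the final models
#'
#' Ranks all generated structures by restraint-free energy, takes the 10
#' lowest, applies full-atom optimization (side-chain repack plus
#' unrestrained minimization) and re-sorts. Restraint-free energy is the
#' protocol's final scoring function.
#'
#' @param all_trials List of scored trials (across all cycles).
#' @param config Configuration.
#' @param n_final Number of models to return (default 10).
#' @param seed Seed for the repacks.
#' @return List of `protein_model`s (provenance `"final"`, attribute
#'   `final_energy` per model), ascending energy.
#' @export
select_final_models <- function(all_trials, config = default_config(),
                                n_final = 10L, seed = config$seed) {
  if (length(all_trials) < n_final) {
    warning("fewer than ", n_final, " scored structures; returning all")
    n_final <- length(all_trials)
  }
  en <- vapply(all_trials, `[[`, numeric(1), "energy_norestr")
  sel <- order(en)[seq_len(n_final)]
  polished <- lapply(seq_along(sel), function(q) {
    m <- all_trials[[sel[q]]]$model
    m <- repack_sidechains(m, config, seed = split_seed(seed, 7000L + q))
    m <- relax(m, NULL, relax_schedule(config$steps_standard, "minimize"),
               config)
    m$provenance <- "final"
    attr(m, "final_energy") <- evaluate_energy(m, NULL, config)$total_without_restraints
    attr(m, "pre_optimization") <- all_trials[[sel[q]]]$model
    m
  })
  polished[order(vapply(polished, attr, numeric(1), "final_energy"))]
}

#' Run the full refinement protocol
#'
#' Pre-processing (residue-error estimation and ULR detection; optional
#' homolog threading and patch harvesting) followed by the pool-based
#' conformational search and restraint-free final selection. Deterministic
#' given `config$seed`.
#'
#' @param input A `protein_model` (<= 300 residues, no internal breaks).
#' @param config Configuration; `config$mode = "conservative"` switches to
#'   harmonic restraints with 5% neglect.
#' @param pssm Optional PSSM matrix (positions x 20).
#' @param fraglib Optional `fragment_library` (defaults to one harvested
#'   from the input model plus noise fragments).
#' @param homologs Optional list of `list(model, alignment)` homolog
#'   structures with alignments.
#' @param restraint_source Optional `protein_model` to build restraints
#'   from instead of the input (oracle-restraint test mode).
#' @param profile Optional precomputed `residue_error_profile`.
#' @return A `refinement_result`: `final_models`, `log` (per-cycle data
#'   frame), `all_scored_count`, `profile`, `restraints`, `input`.
#' @export
run_refinement <- function(input, config = default_config(), pssm = NULL,
                           fraglib = NULL, homologs = NULL,
                           restraint_source = NULL, profile = NULL) {
  rep_v <- validate_input(input)
  fatal <- setdiff(rep_v$violations, "OVER_LENGTH")
  if (length(fatal))
    stop("input fails validation: ", paste(fatal, collapse = ", "))
  if ("OVER_LENGTH" %in% rep_v$violations)
    warning("input exceeds ", config$max_residues,
            " residues; proceeding (library mode)")
  seed <- config$seed
  restraints <- build_restraints(restraint_source %||% input, config = config)
  fraglib <- fraglib %||% make_fragment_library(input, config$frag_window,
                                                seed = split_seed(seed, 2L))
  if (is.null(profile))
    profile <- estimate_residue_errors(input, fraglib = fraglib, pssm = pssm,
                                       restraints = restraints,
                                       config = config,
                                       seed = split_seed(seed, 3L))

  patch_library <- NULL
  if (!is.null(homologs) && length(homologs)) {
    threaded <- list()
    for (h in homologs) {
      if (alignment_coverage(h$alignment) < config$min_coverage) next
      thr <- tryCatch(thread_sequence(model_sequence(input), h$model,
                                      h$alignment, config,
                                      seed = split_seed(seed, 4L)),
                      error = function(e) NULL)
      if (!is.null(thr)) threaded[[length(threaded) + 1L]] <- thr
    }
    threaded <- filter_homologs_by_tmscore(threaded, input,
                                           config$tm_threshold)
    if (length(threaded)) {
      opt <- lapply(seq_along(threaded), function(k)
        optimize_threaded(threaded[[k]], config, seed = split_seed(seed, 50L + k)))
      patch_library <- extract_patch_library(
        opt, profile$ulrs, c(config$patch_min, config$patch_max),
        config$patch_stride)
    }
  }

  context <- operator_context(profile, fraglib = fraglib,
                              patch_library = patch_library,
                              rng_seed = seed, config = config)
  pool <- initialize_pool(input, profile, restraints, config, fraglib,
                          seed = split_seed(seed, 5L))
  all_trials <- list()
  log <- data.frame()
  for (cy in seq_len(config$cycles)) {
    trials <- generate_trials(pool, context, restraints, config,
                              seed = split_seed(seed, 600L + cy))
    pool <- update_pool(pool, trials, config)
    all_trials <- c(all_trials, trials)
    pe <- vapply(pool$members, `[[`, numeric(1), "energy")
    ops <- table(vapply(trials, `[[`, character(1), "operator"))
    log <- rbind(log, data.frame(
      cycle = cy, min_energy = min(pe), mean_energy = mean(pe),
      accepted = pool$accepted, closeness_radius = pool$closeness_radius,
      operators = paste(sprintf("%s:%d", names(ops), as.integer(ops)),
                        collapse = ",")))
  }
  finals <- select_final_models(all_trials, config,
                                seed = split_seed(seed, 6L))
  structure(list(final_models = finals, log = log,
                 all_scored_count = length(all_trials),
                 profile = profile, restraints = restraints, input = input,
                 config = config),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result> %d models from %d scored trials over %d cycles\n",
              length(x$final_models), x$all_scored_count, nrow(x$log)))
  for (i in seq_along(x$final_models))
    cat(sprintf("  model_%02d  E(no restraints) = %.3f\n", i,
                attr(x$final_models[[i]], "final_energy")))
  invisible(x)
}

#' Write refinement outputs to a directory
#'
#' Writes `model_01.pdb` ... `model_10.pdb`, a `report.tsv` (per-model
#' restraint-free energy, CA-RMSD to the input, clash score, favored
#' backbone-torsion percentage) and `log.jsonl` (one JSON object per
#' cycle).
#'
#' @param result A `refinement_result`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_refinement_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_final_models(result$final_models, dir)
  rep <- do.call(rbind, lapply(seq_along(result$final_models), function(i) {
    m <- result$final_models[[i]]
    data.frame(model = sprintf("model_%02d", i),
               energy_norestr = attr(m, "final_energy"),
               ca_rmsd_to_input = ca_rmsd(m, result$input),
               clash_per_1000 = clash_score(m),
               rama_favored_pct = 100 * rama_favored(m))
  }))
  utils::write.table(rep, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  con <- file(file.path(dir, "log.jsonl"), "w")
  for (i in seq_len(nrow(result$log)))
    writeLines(jsonlite::toJSON(as.list(result$log[i, ]), auto_unbox = TRUE),
               con)
  close(con)
  invisible(dir)
}
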