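#' Demographic model for coalescent simulation
#'
#' A population-split tree with one constant diploid effective size per
#' population and timed, directed per-generation migration pulses. Time is
#' counted in generations before present (BP). A pulse with
#' `start_gen_bp = T` and `duration_gens = d` begins (forward in time) at
#' generation T BP and runs for d generations toward the present, i.e. it
#' acts at backward-time generations `T-d+1, ..., T`; during each of those
#' generations every lineage of `dest` has probability `rate_per_gen` of
#' originating from `source`.
#'
#' @param populations data.frame with columns `name` and `ne` (diploid Ne).
#' @param splits data.frame with columns `time` (generations BP), `derived`,
#'   `ancestral`: looking backward, at `time` the derived population merges
#'   into the ancestral one.
#' @param pulses optional data.frame with columns `source`, `dest`,
#'   `start_gen_bp`, `duration_gens`, `rate_per_gen`.
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param recombination_rate per-bp per-generation recombination rate
#'   (informational; loci are simulated without intra-locus recombination —
#'   see `subloci` in [simulate_genotypes()]).
#' @param generation_years years per generation (informational).
#' @return a validated `demographic_model`.
#' @export
demographic_model <- function(populations, splits, pulses = NULL,
                              mutation_rate = 1e-8,
                              recombination_rate = 1e-8,
                              generation_years = 5) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "ne") %in% names(populations)))
  populations$name <- as.character(populations$name)
  populations$ne <- as.numeric(populations$ne)
  if (anyDuplicated(populations$name)) stop("duplicated population name")
  if (any(populations$ne <= 0)) stop("effective sizes must be positive")

  splits <- as.data.frame(splits, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "derived", "ancestral") %in% names(splits)))
  splits$time <- as.numeric(splits$time)
  splits$derived <- as.character(splits$derived)
  splits$ancestral <- as.character(splits$ancestral)
  if (any(splits$time <= 0)) stop("split times must be strictly positive")
  if (anyDuplicated(splits$derived))
    stop("a population may split from its ancestor only once")
  known <- populations$name
  if (!all(c(splits$derived, splits$ancestral) %in% known))
    stop("split references an unknown population")
  # topological consistency: ancestor must still exist (not yet merged away)
  # at the split time, looking backward
  anc_end <- setNames(rep(Inf, length(known)), known)
  anc_end[splits$derived] <- splits$time
  if (any(splits$time > anc_end[splits$ancestral]))
    stop("split into a population that has already merged away")
  # exactly one root: population that never appears as derived
  roots <- setdiff(known, splits$derived)
  if (length(roots) != 1)
    stop("model must have exactly one root population; found: ",
         paste(roots, collapse = ", "))

  if (!is.null(pulses) && nrow(as.data.frame(pulses)) > 0) {
    pulses <- as.data.frame(pulses, stringsAsFactors = FALSE)
    stopifnot(all(c("source", "dest", "start_gen_bp", "duration_gens",
                    "rate_per_gen") %in% names(pulses)))
    if (any(pulses$rate_per_gen <= 0 | pulses$rate_per_gen >= 1))
      stop("pulse rates must lie strictly between 0 and 1")
    if (any(pulses$duration_gens < 1)) stop("pulse duration must be >= 1")
    if (!all(c(pulses$source, pulses$dest) %in% known))
      stop("pulse references an unknown population")
  } else pulses <- NULL

  structure(list(populations = populations,
                 splits = splits[order(splits$time), ],
                 pulses = pulses,
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate,
                 generation_years = generation_years),
            class = "demographic_model")
}

#' @method print demographic_model
#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model: %d populations, %d splits, %d pulses\n",
              nrow(x$populations), nrow(x$splits),
              if (is.null(x$pulses)) 0L else nrow(x$pulses)))
  invisible(x)
}

#' Leaf populations of a model
#'
#' Populations that never act as the ancestral side of a split, i.e. the
#' sampleable present-day isolates.
#' @param model a [demographic_model()].
#' @return character vector of population names.
#' @export
leaf_populations <- function(model) {
  setdiff(model$populations$name, model$splits$ancestral)
}

#' Scenario specification for the Eurasian pig demography
#'
#' The four introgression scenarios studied on the simulated history:
#' I = gene flow from EUD breeds into EUW groups; II = from EUW into EUD;
#' III = as I plus ASD-to-EUD flow; IV = as II plus ASD-to-EUD flow.
#'
#' @param scenario one of "I", "II", "III", "IV".
#' @param euw_eud_rate per-generation migration rate between the paired
#'   EUW/EUD populations: 0.02, 0.04 or 0.06.
#' @param n_loci number of independent 50 kb-like regions.
#' @param locus_length region length in bp.
#' @param chroms_per_pop haploid chromosomes sampled per population (even).
#' @param seed integer seed.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("I", "II", "III", "IV"),
                          euw_eud_rate = 0.02, n_loci = 1000L,
                          locus_length = 50000L, chroms_per_pop = 40L,
                          seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(euw_eud_rate > 0, euw_eud_rate < 1,
            n_loci >= 1, locus_length >= 1,
            chroms_per_pop >= 2, chroms_per_pop %% 2 == 0)
  structure(list(scenario = scenario, euw_eud_rate = euw_eud_rate,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 chroms_per_pop = as.integer(chroms_per_pop),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Demographic model of Eurasian pig history
#'
#' Builds the simulated history of European and Chinese *Sus scrofa*:
#' an ancestral population (Ne 10,000) from which the Sumatran outgroup
#' (Ne 10,000) splits deepest, then the European (Ne 175,000) and Asian
#' (Ne 170,000) stems; each stem splits into wild and domestic populations
#' (EUW Ne 8,000, EUD Ne 20,000, ASW Ne 36,000, ASD Ne 26,000); and
#' recent breed/group formation isolates 8 European breeds from EUD,
#' 7 European wild boar groups from EUW, 3 Asian breeds from ASD and 1
#' Asian wild boar group from ASW, each at Ne 2,000, at times evenly spaced
#' over 40-60 generations BP. Asian-to-European gene flow (scenarios III
#' and IV) sends migrants from ASD1 into the first six European breeds for
#' 10 generations starting 40 generations BP at per-breed rates alternating
#' 1% and 2%; wild/domestic gene flow (all scenarios) links the first five
#' breed/group pairs for 10 generations starting 30 generations BP at
#' `euw_eud_rate`, directed per the scenario.
#'
#' Split times not determined by the recent breed history default to:
#' wild/domestic splits 2,000 generations BP (about 10,000 years at 5
#' years/generation), Europe-Asia split 200,000 and Sumatran outgroup
#' 300,000 generations BP.
#'
#' @param spec a [scenario_spec()].
#' @param wild_domestic_split,eu_as_split,outgroup_split generations BP.
#' @return a [demographic_model()].
#' @export
build_pig_model <- function(spec, wild_domestic_split = 2000,
                            eu_as_split = 200000, outgroup_split = 3e5) {
  eud_breeds <- paste0("EUD", 1:8)
  asd_breeds <- paste0("ASD", 1:3)
  euw_groups <- paste0("EUW", 1:7)
  asw_groups <- "ASW1"
  pops <- rbind(
    data.frame(name = "ANC", ne = 10000),
    data.frame(name = "Sum", ne = 10000),
    data.frame(name = "EU", ne = 175000),
    data.frame(name = "AS", ne = 170000),
    data.frame(name = "EUD", ne = 20000),
    data.frame(name = "EUW", ne = 8000),
    data.frame(name = "ASD", ne = 26000),
    data.frame(name = "ASW", ne = 36000),
    data.frame(name = c(eud_breeds, asd_breeds, euw_groups, asw_groups),
               ne = 2000))
  iso_times <- function(nms) {
    t <- if (length(nms) == 1) 50 else seq(40, 60, length.out = length(nms))
    data.frame(time = t, derived = nms,
               ancestral = sub("[0-9]+$", "", nms))
  }
  splits <- rbind(
    iso_times(eud_breeds), iso_times(asd_breeds),
    iso_times(euw_groups), iso_times(asw_groups),
    data.frame(time = wild_domestic_split,
               derived = c("EUD", "EUW", "ASD", "ASW"),
               ancestral = c("EU", "EU", "AS", "AS")),
    data.frame(time = eu_as_split, derived = c("EU", "AS"),
               ancestral = c("ANC", "ANC")),
    data.frame(time = outgroup_split, derived = "Sum", ancestral = "ANC"))

  pulses <- NULL
  if (spec$scenario %in% c("III", "IV")) {
    pulses <- data.frame(source = "ASD1", dest = eud_breeds[1:6],
                         start_gen_bp = 40, duration_gens = 10,
                         rate_per_gen = rep(c(0.01, 0.02), 3))
  }
  wd <- if (spec$scenario %in% c("I", "III"))
    data.frame(source = eud_breeds[1:5], dest = euw_groups[1:5],
               start_gen_bp = 30, duration_gens = 10,
               rate_per_gen = spec$euw_eud_rate)
  else
    data.frame(source = euw_groups[1:5], dest = eud_breeds[1:5],
               start_gen_bp = 30, duration_gens = 10,
               rate_per_gen = spec$euw_eud_rate)
  pulses <- rbind(pulses, wd)

  demographic_model(pops, splits, pulses,
                    mutation_rate = 1e-8, recombination_rate = 1e-8,
                    generation_years = 5)
}
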