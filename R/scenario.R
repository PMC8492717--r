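#' Demographic scenario (population-split program)
#'
#' A scenario is a backwards-in-time event program over a set of named
#' populations (conventionally metapopulations such as `ME`, `MP`,
#' `IS`).  Each event `split derived source @ t` moves every lineage of
#' `derived` into `source` at the time drawn for symbol `t` (generations
#' before present).  Effective sizes are haploid gene-copy counts (the
#' natural unit for maternally inherited mtDNA — not 2N).  Ordering
#' constraints such as `t2 > t1` restrict the joint prior.
#'
#' @param id scenario identifier string.
#' @param pops character vector of extant population names.
#' @param ne named character vector: population -> effective-size
#'   symbol.
#' @param events data frame with columns `derived`, `source`, `time`
#'   (time symbols).
#' @param constraints list of length-3 character vectors
#'   `c(lhs, ">", rhs)`.
#' @return An object of class `mt_scenario`.
#' @export
scenario <- function(id, pops, ne, events, constraints = list()) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  stopifnot(all(c("derived", "source", "time") %in% names(events)))
  if (!all(names(ne) %in% pops) || !all(pops %in% names(ne)))
    stop("`ne` must name exactly the populations", call. = FALSE)
  if (!all(events$derived %in% pops) || !all(events$source %in% pops))
    stop("event populations must be among `pops`", call. = FALSE)
  ## the program must funnel everything into a single ancestral pop:
  ## each population may be derived at most once, and exactly
  ## length(pops) - 1 splits are needed
  if (nrow(events) != length(pops) - 1L || anyDuplicated(events$derived))
    stop("event program must coalesce all populations into one", call. = FALSE)
  structure(list(id = id, pops = pops, ne = ne, events = events,
                 constraints = constraints),
            class = "mt_scenario")
}

#' @export
print.mt_scenario <- function(x, ...) {
  cat("scenario", x$id, ": pops", paste(x$pops, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$events)))
    cat(sprintf("  split %s -> %s @ %s\n", x$events$derived[i],
                x$events$source[i], x$events$time[i]))
  for (cc in x$constraints) cat("  constraint", paste(cc, collapse = " "), "\n")
  invisible(x)
}

## all prior symbols a scenario draws
.scenario_symbols <- function(s) unique(c(unname(s$ne), s$events$time))

#' Prior specification for scenario parameters
#'
#' Named list of marginal priors: each entry is
#' `list(dist = "unif" | "logunif", min = , max = )`.  Two names are
#' special: `mu`, the per-site per-generation mutation rate, and
#' `kappa`, the HKY transition/transversion ratio.  Effective sizes are
#' gene copies; times are generations before present.
#'
#' @param ... named prior entries (see above); unlisted size/time
#'   symbols fall back to `default_ne` / `default_t`.
#' @param default_ne,default_t fallback priors.
#' @return `mt_priors` object (a named list with a fallback rule).
#' @export
prior_spec <- function(...,
                       default_ne = list(dist = "unif", min = 1e2, max = 1e5),
                       default_t = list(dist = "unif", min = 1e2, max = 2e4)) {
  pri <- list(...)
  if (length(pri) && (is.null(names(pri)) || any(names(pri) == "")))
    stop("all prior entries must be named", call. = FALSE)
  if (is.null(pri$mu)) pri$mu <- list(dist = "logunif", min = 1e-8, max = 1e-7)
  if (is.null(pri$kappa)) pri$kappa <- list(dist = "unif", min = 2, max = 20)
  for (nm in names(pri)) {
    p <- pri[[nm]]
    ## point masses (min == max) are allowed for degenerate testing
    if (!all(c("dist", "min", "max") %in% names(p)) || p$min <= 0 ||
        !is.finite(p$max) || p$max < p$min)
      stop("invalid prior for '", nm, "': need finite positive bounds",
           call. = FALSE)
  }
  if (pri$mu$max < 1e-8 || pri$mu$min > 1e-7)
    warning("mutation-rate prior does not intersect [1e-8, 1e-7] per site ",
            "per generation; check units")
  structure(list(priors = pri, default_ne = default_ne, default_t = default_t),
            class = "mt_priors")
}

.prior_for <- function(priors, symbol) {
  if (!is.null(priors$priors[[symbol]])) return(priors$priors[[symbol]])
  if (grepl("^[Nn]", symbol)) priors$default_ne else priors$default_t
}

.draw_prior <- function(p, n = 1L) {
  switch(p$dist,
         unif = stats::runif(n, p$min, p$max),
         logunif = exp(stats::runif(n, log(p$min), log(p$max))),
         stop("unknown prior family '", p$dist, "'", call. = FALSE))
}

.check_constraints <- function(s, vals) {
  for (cc in s$constraints) {
    lhs <- vals[[cc[1]]]; rhs <- vals[[cc[3]]]
    ok <- switch(cc[2], ">" = lhs > rhs, "<" = lhs < rhs,
                 ">=" = lhs >= rhs, "<=" = lhs <= rhs,
                 stop("unknown constraint operator ", cc[2], call. = FALSE))
    if (!ok) return(cc)
  }
  NULL
}

#' Draw one parameter vector for a scenario from its priors
#'
#' Ordering constraints are enforced by rejection re-draws.
#'
#' @param s an `mt_scenario`.
#' @param priors an `mt_priors`.
#' @param max_tries rejection cap before erroring.
#' @return Named list of drawn values (sizes, times, `mu`, `kappa`).
#' @export
draw_params <- function(s, priors, max_tries = 1000L) {
  syms <- .scenario_symbols(s)
  for (tr in seq_len(max_tries)) {
    vals <- lapply(syms, function(sym) .draw_prior(.prior_for(priors, sym)))
    names(vals) <- syms
    vals$mu <- .draw_prior(priors$priors$mu)
    vals$kappa <- .draw_prior(priors$priors$kappa)
    bad <- .check_constraints(s, vals)
    if (is.null(bad)) return(vals)
  }
  stop("prior region unreachable: constraint ", paste(bad, collapse = " "),
       " failed ", max_tries, " consecutive draws", call. = FALSE)
}

#' Built-in colonization scenario presets
#'
#' `"lineageA"` contrasts a Middle-East-source stepping-stone scenario
#' (`1_ME`: ME seeds MP, MP seeds IS) with an Indian-subcontinent-source
#' scenario (`4_IS`: IS seeds ME first, then MP).  `"lineageB"`
#' contrasts the inland route (`1_inland`, same topology as `1_ME`) with
#' an independent maritime colonization of IS from ME (`2_sea`), whose
#' split time `t4` is left unconstrained relative to `t1` because the
#' order of divergence is unknown.
#'
#' @param preset `"lineageA"` or `"lineageB"`.
#' @return List of `mt_scenario` objects.
#' @export
default_scenarios <- function(preset = c("lineageA", "lineageB")) {
  preset <- match.arg(preset)
  pops <- c("ME", "MP", "IS")
  ne <- c(ME = "NME", MP = "NMP", IS = "NIS")
  if (preset == "lineageA") {
    list(
      scenario("1_ME", pops, ne,
               data.frame(derived = c("IS", "MP"), source = c("MP", "ME"),
                          time = c("t1", "t2")),
               list(c("t2", ">", "t1"))),
      scenario("4_IS", pops, ne,
               data.frame(derived = c("MP", "ME"), source = c("IS", "IS"),
                          time = c("t1", "t2")),
               list(c("t2", ">", "t1"))))
  } else {
    list(
      scenario("1_inland", pops, ne,
               data.frame(derived = c("IS", "MP"), source = c("MP", "ME"),
                          time = c("t1", "t2")),
               list(c("t2", ">", "t1"))),
      scenario("2_sea", pops, ne,
               data.frame(derived = c("MP", "IS"), source = c("ME", "ME"),
                          time = c("t1", "t4")),
               list()))
  }
}

#' Parse a scenario definition file
#'
#' Structured text, one block per scenario:
#' \preformatted{
#' scenario 1_ME
#' pops ME MP IS
#' ne NME NMP NIS
#' split IS MP @ t1
#' split MP ME @ t2
#' constraint t2 > t1
#' end
#' }
#'
#' @param path file path.
#' @return List of `mt_scenario` objects.
#' @export
parse_scenarios <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list(); cur <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    kw <- tok[1]
    if (kw == "scenario") {
      cur <- list(id = tok[2], pops = NULL, ne = NULL,
                  events = NULL, constraints = list())
    } else if (is.null(cur)) {
      stop("config error: '", ln, "' outside a scenario block", call. = FALSE)
    } else if (kw == "pops") {
      cur$pops <- tok[-1]
    } else if (kw == "ne") {
      cur$ne <- stats::setNames(tok[-1], cur$pops)
    } else if (kw == "split") {
      if (length(tok) != 5L || tok[4] != "@")
        stop("config error: bad split line '", ln, "'", call. = FALSE)
      cur$events <- rbind(cur$events,
                          data.frame(derived = tok[2], source = tok[3],
                                     time = tok[5]))
    } else if (kw == "constraint") {
      cur$constraints <- c(cur$constraints, list(tok[c(2, 3, 4)]))
    } else if (kw == "end") {
      out[[cur$id]] <- scenario(cur$id, cur$pops, cur$ne, cur$events,
                                cur$constraints)
      cur <- NULL
    } else stop("config error: unknown keyword '", kw, "'", call. = FALSE)
  }
  unname(out)
}

#' Parse a prior definition file
#'
#' One line per symbol: `name dist min max`, e.g.
#' `NME unif 100 100000` or `mu logunif 1e-8 1e-7`.
#'
#' @param path file path.
#' @return An `mt_priors`.
#' @export
parse_priors <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  pri <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != 4L)
      stop("config error: bad prior line '", ln, "'", call. = FALSE)
    pri[[tok[1]]] <- list(dist = tok[2], min = as.numeric(tok[3]),
                          max = as.numeric(tok[4]))
  }
  do.call(prior_spec, pri)
}
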