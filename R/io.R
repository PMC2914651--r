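#' Read a reaction-network model file
#'
#' Model files are JSON (or YAML, by extension `.yml`/`.yaml`) with the
#' schema:
#' \preformatted{
#' {
#'   "species": ["A", "B"],
#'   "reactions": [
#'     {"name": "R1", "reactants": {"A": 1}, "products": {},
#'      "rate_law": "mass_action", "theta": 0.03}
#'   ],
#'   "conserved": [{"species": ["A", "B"], "total": 10}],
#'   "convention": "binomial"
#' }
#' }
#' `reactants`/`products` map species names to integer stoichiometries;
#' `rate_law` defaults to `"mass_action"`; `conserved` and `convention` are
#' optional. Validation is strict and delegates to [reaction_network()].
#'
#' @param path model file.
#' @return a [reaction_network()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML models requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  if (is.null(spec$species) || is.null(spec$reactions))
    stop(path, ": model file must list 'species' and 'reactions'",
         call. = FALSE)
  rx <- lapply(spec$reactions, function(r) {
    list(name = r$name,
         reactants = unlist(r$reactants) %||% c(),
         products = unlist(r$products) %||% c(),
         rate_law = r$rate_law %||% "mass_action",
         theta = r$theta)
  })
  reaction_network(species = unlist(spec$species), reactions = rx,
                   conserved = spec$conserved,
                   convention = spec$convention %||% "binomial")
}

#' Write a reaction network to a model file
#'
#' Round-trips with [read_model()].
#'
#' @param network a mass-action [reaction_network()] (custom hazard
#'   functions cannot be serialized).
#' @param path output path (`.json`, `.yml` or `.yaml`).
#' @export
write_model <- function(network, path) {
  if (!is_mass_action(network))
    stop("only mass-action networks can be serialized", call. = FALSE)
  named_stoich <- function(row) {
    row <- setNames(as.integer(row), network$species)
    nz <- row[row > 0]
    if (!length(nz)) return(structure(list(), names = character(0)))
    as.list(nz)
  }
  spec <- list(
    species = as.list(network$species),
    reactions = lapply(seq_along(network$reactions), function(r) {
      list(name = network$reactions[r],
           reactants = named_stoich(network$U[r, ]),
           products = named_stoich(network$V[r, ]),
           rate_law = unname(network$rate_law[r]),
           theta = unname(network$theta[r]))
    }),
    convention = network$convention
  )
  if (!is.null(network$conserved)) spec$conserved <- network$conserved
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(spec, path)
  } else {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Write inference results, trace, diagnostics and a run manifest
#'
#' Emits four files into `outdir`: `results.json` (estimates, Monte-Carlo
#' standard errors of the final gradient, iteration count, convergence
#' flag), `trace.csv` (the full per-iteration SGD trace), `diagnostics.csv`
#' (sampler acceptance counts), and `manifest.json` (settings, seed,
#' package version, input digests and a timestamp — enough to reproduce the
#' run). Files are written atomically (temp file + rename).
#'
#' @param fit an `sgd_fit` from [infer_parameters()].
#' @param outdir output directory (created if missing).
#' @param inputs optional named character vector of input file paths whose
#'   MD5 digests are recorded in the manifest.
#' @return invisibly, the paths written.
#' @export
write_results <- function(fit, outdir, inputs = NULL) {
  stopifnot(inherits(fit, "sgd_fit"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  atomically <- function(name, writer) {
    final <- file.path(outdir, name)
    tmp <- paste0(final, ".tmp")
    writer(tmp)
    file.rename(tmp, final)
    final
  }
  res <- list(
    theta_hat = as.list(fit$theta_hat),
    gradient = as.list(setNames(fit$gradient$estimate,
                                fit$gradient$reaction)),
    std_error = as.list(setNames(fit$gradient$std_error,
                                 fit$gradient$reaction)),
    iterations = fit$iterations,
    converged = fit$converged,
    observed = fit$observed,
    seed = fit$seed
  )
  p1 <- atomically("results.json", function(f)
    jsonlite::write_json(res, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  p2 <- atomically("trace.csv", function(f)
    write.csv(as.data.frame(fit$trace), f, row.names = FALSE))
  p3 <- atomically("diagnostics.csv", function(f)
    write.csv(as.data.frame(fit$accept), f, row.names = FALSE))
  manifest <- list(
    package = "sgdkinetics",
    version = as.character(utils::packageVersion("sgdkinetics")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = fit$seed,
    sgd = unclass(fit$sgd),
    mcmc = unclass(fit$mcmc),
    observed = fit$observed,
    inputs = if (!is.null(inputs))
      as.list(setNames(tools::md5sum(inputs), names(inputs) %||% inputs))
  )
  p4 <- atomically("manifest.json", function(f)
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  invisible(c(results = p1, trace = p2, diagnostics = p3, manifest = p4))
}
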