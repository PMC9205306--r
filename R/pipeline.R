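#' Configuration of a single-site analysis
#'
#' @param transform trait names to log10-transform (site-specific: the
#'   hand-picked exceptions differ between forests).
#' @param alpha_size significance level of the biomass slope test.
#' @param alpha_edge significance level for network edges.
#' @param size_regressor `"log10"` or `"raw"` biomass in the size
#'   correction.
#' @param spinglass list of annealer settings passed to
#'   [spinglass_partition()] (`spins`, `gamma`, `start_temp`, `stop_temp`,
#'   `cool_fact`, `n_runs`).
#' @param seed master seed; every stochastic stage derives its own stream
#'   via [sub_seed()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(transform = character(), alpha_size = 0.05,
                       alpha_edge = 0.05, size_regressor = "log10",
                       spinglass = list(), seed = 1) {
  stopifnot(alpha_size > 0, alpha_size < 1, alpha_edge > 0, alpha_edge <= 1)
  sg <- list(spins = 25, gamma = 1, start_temp = 1, stop_temp = 0.01,
             cool_fact = 0.99, n_runs = 10)
  sg[names(spinglass)] <- spinglass
  structure(list(transform = transform, alpha_size = alpha_size,
                 alpha_edge = alpha_edge, size_regressor = size_regressor,
                 spinglass = sg, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, cfg)
}

#' Run the full single-site analysis
#'
#' Fixed stage order: log10 transform, size correction against biomass,
#' then two branches — (A) pairwise correlations, significance-thresholded
#' network, spin-glass modules, centralities and PC1 importance; (B) when a
#' tree is given, independent contrasts, their correlations and their PCA.
#' Degenerate networks (too few connected traits, or a constant centrality
#' metric) do not fail the run: the importance element is `NULL` with an
#' explanatory `note`.
#'
#' @param table a [trait_table()] of species means.
#' @param config a [run_config()].
#' @param tree optional rooted `phylo`; prepared with [prepare_tree()]
#'   (random polytomy resolution, unit branch lengths).
#' @param out_dir optional directory; when given, every artifact is written
#'   as CSV/GraphML/Newick plus a JSON `manifest.json` with parameters,
#'   seeds and per-stage sizes.
#' @return A list with `table` (processed), `size_correction`, `normality`,
#'   `correlations`, `network`, `partition`, `centralities`, `importance`
#'   (or `NULL` + `importance_note`), `pca_traits`, and when a tree was
#'   given `prepared_tree`, `pic`, `pic_correlations`, `pca_pic`; plus
#'   `manifest`.
#' @export
run_site <- function(table, config = run_config(), tree = NULL,
                     out_dir = NULL) {
  stopifnot(inherits(table, "trait_table"), inherits(config, "run_config"))
  table <- log_transform(table, config$transform)
  normality <- attr(table, "normality")
  size_rep <- NULL
  if (!is.null(table$biomass)) {
    table <- size_correct(table, alpha = config$alpha_size,
                          regressor = config$size_regressor)
    size_rep <- attr(table, "size_correction")
  }
  corr <- pearson_pairwise(table)
  net <- build_network(corr, alpha = config$alpha_edge)
  partition <- if (igraph::ecount(net) > 0)
    do.call(spinglass_partition,
            c(list(net = net, seed = sub_seed(config$seed, "spinglass")),
              stats::setNames(config$spinglass, names(config$spinglass))))
  else NULL
  cent <- centrality_table(net)
  imp <- tryCatch(importance_scores(cent), error = function(e) e)
  importance_note <- NULL
  if (inherits(imp, "error")) {
    importance_note <- paste("insufficient network:", conditionMessage(imp))
    imp <- NULL
  }
  pca_traits <- tryCatch(pca(table$values, standardize = TRUE),
                         error = function(e) NULL)

  out <- list(table = table, size_correction = size_rep,
              normality = normality, correlations = corr, network = net,
              partition = partition, centralities = cent,
              importance = imp, importance_note = importance_note,
              pca_traits = pca_traits)

  if (!is.null(tree)) {
    ptree <- prepare_tree(tree, species = table$species_id,
                          seed = sub_seed(config$seed, "polytomy"))
    pics <- pic_matrix(ptree, table)
    out$prepared_tree <- attr(pics, "tree")
    out$pic <- pics
    out$pic_correlations <- pic_correlations(pics)
    out$pca_pic <- tryCatch(pca(pics, standardize = TRUE),
                            error = function(e) NULL)
  }

  out$manifest <- list(
    site = table$site,
    n_species = nrow(table$values), n_traits = ncol(table$values),
    transform = config$transform, alpha_size = config$alpha_size,
    alpha_edge = config$alpha_edge, size_regressor = config$size_regressor,
    spinglass = config$spinglass, seed = config$seed,
    seeds = list(spinglass = sub_seed(config$seed, "spinglass"),
                 polytomy = sub_seed(config$seed, "polytomy")),
    n_edges = igraph::ecount(net),
    Q = if (is.null(partition)) NA_real_ else partition$Q,
    package_version = as.character(utils::packageVersion("traitnet")))

  if (!is.null(out_dir)) write_site_artifacts(out, out_dir)
  out
}

# internal: write every artifact of a site run under out_dir
write_site_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_trait_table(run$table, p("traits_processed.csv"))
  utils::write.csv(run$correlations, p("correlations.csv"), row.names = FALSE)
  if (!is.null(run$size_correction))
    utils::write.csv(run$size_correction, p("size_correction.csv"),
                     row.names = FALSE)
  write_network(run$network, p("network.graphml"))
  write_network(run$network, p("network_edges.csv"))
  utils::write.csv(run$centralities, p("centralities.csv"), row.names = FALSE)
  if (!is.null(run$partition))
    utils::write.csv(data.frame(trait = names(run$partition$membership),
                                module = unname(run$partition$membership)),
                     p("modules.csv"), row.names = FALSE)
  if (!is.null(run$importance))
    utils::write.csv(data.frame(trait = names(run$importance$scores),
                                pc1 = unname(run$importance$scores)),
                     p("importance.csv"), row.names = FALSE)
  if (!is.null(run$pic)) {
    utils::write.csv(as.data.frame(run$pic), p("pic_contrasts.csv"),
                     row.names = TRUE)
    ape::write.tree(run$prepared_tree, p("tree_prepared.nwk"))
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Compare two completed site runs
#'
#' Every trait pair defined at both sites is compared with the Fisher
#' r-to-z test using each site's pairwise-complete `r` and `n`; the result
#' is sorted by ascending p-value. Importance (PC1) scores are correlated
#' across shared traits, and the centrality tables are laid out
#' side-by-side.
#'
#' @param run_a,run_b results of [run_site()].
#' @return A list with `correlation_comparison` (data.frame, ascending p),
#'   `importance_comparison` (`r`, `r2`, `p`, or `NULL` + note when either
#'   site lacks an importance result) and `centrality_comparison`.
#' @export
compare_sites <- function(run_a, run_b) {
  shared <- intersect(traits(run_a$table), traits(run_b$table))
  if (length(shared) < 4) stop("fewer than 4 shared traits between sites")
  key <- function(d) paste(pmin(d$trait_a, d$trait_b),
                           pmax(d$trait_a, d$trait_b), sep = "|")
  ca <- run_a$correlations; cb <- run_b$correlations
  m <- match(key(ca), key(cb))
  ok <- !is.na(m) & !is.na(ca$r) & !is.na(cb$r[m]) &
    ca$n >= 4 & cb$n[m] >= 4 & abs(ca$r) < 1 & abs(cb$r[m]) < 1
  if (!any(ok)) stop("no comparable trait pair between sites")
  cmp <- cbind(ca[ok, c("trait_a", "trait_b")],
               compare_correlations(ca$r[ok], ca$n[ok],
                                    cb$r[m][ok], cb$n[m][ok]))
  cmp <- cmp[order(cmp$p), ]
  rownames(cmp) <- NULL

  imp <- NULL; imp_note <- NULL
  if (!is.null(run_a$importance) && !is.null(run_b$importance)) {
    imp <- tryCatch(compare_importance(run_a$importance, run_b$importance),
                    error = function(e) { imp_note <<- conditionMessage(e); NULL })
  } else imp_note <- "importance unavailable for at least one site"

  cent <- merge(run_a$centralities, run_b$centralities, by = "trait",
                suffixes = c("_a", "_b"), all = TRUE)
  list(correlation_comparison = cmp, importance_comparison = imp,
       importance_note = imp_note, centrality_comparison = cent)
}

#' Published two-forest centrality table
#'
#' The printed per-trait degree, betweenness and closeness values for the
#' moist- and dry-forest trait networks (10 traits each), shipped with the
#' package as a plain-text CSV. These are the inputs to the desk-scale
#' re-analysis of trait importance (see [importance_scores()]).
#'
#' @return A data.frame with columns `trait`, `forest`, `betweenness`,
#'   `closeness`, `degree`.
#' @export
published_centralities <- function() {
  utils::read.csv(system.file("extdata", "published_centralities.csv",
                              package = "traitnet", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
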