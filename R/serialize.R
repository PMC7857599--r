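SCHEMA_VERSION <- "1.0"

mat_to_list <- function(m) {
  list(dim = dim(m), data = as.numeric(t(m))) # row-major
}

list_to_mat <- function(l, logical = FALSE) {
  m <- matrix(l$data, nrow = l$dim[1], ncol = l$dim[2], byrow = TRUE)
  if (logical) m <- m > 0.5
  m
}

#' Write / read an interaction network as JSON
#'
#' Scalars plus dense rate matrices in row-major order, with a schema
#' version field; the generator configuration travels with the network.
#'
#' @param net An `interaction_network`.
#' @param path File path.
#' @return `write_network_json` returns `path` invisibly;
#'   `read_network_json` returns the `interaction_network`.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "interaction_network"))
  obj <- list(schema_version = SCHEMA_VERSION,
              type = "interaction_network",
              n_species = net$n_species, n_mediators = net$n_mediators,
              seed = net$seed,
              basal_rate = net$basal_rate,
              influence_rate = mat_to_list(net$influence_rate),
              production_rate = mat_to_list(net$production_rate),
              consumption_rate = mat_to_list(net$consumption_rate),
              saturation = mat_to_list(net$saturation),
              influence_link = mat_to_list(net$influence_link * 1),
              production_link = mat_to_list(net$production_link * 1),
              resource_K = net$resource_K,
              resource_consumption = net$resource_consumption,
              config = unclass(net$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "interaction_network"))
    stop("not a serialized interaction network")
  cfg <- obj$config
  cfg <- generator_config(
    n_species = cfg$n_species, n_mediators = cfg$n_mediators,
    r0_range = cfg$r0_range, influence_range = cfg$influence_range,
    beta_range = cfg$beta_range, alpha_range = cfg$alpha_range,
    K_range_nM = cfg$K_range_nM, q_p = cfg$q_p, q_c = cfg$q_c,
    f_fac = cfg$f_fac, f_fac_inv = cfg$f_fac_inv,
    q_p_inv = cfg$q_p_inv, q_c_inv = cfg$q_c_inv,
    beta_scale_inv = cfg$beta_scale_inv,
    alpha_scale_inv = cfg$alpha_scale_inv)
  structure(list(n_species = as.integer(obj$n_species),
                 n_mediators = as.integer(obj$n_mediators),
                 basal_rate = obj$basal_rate,
                 influence_rate = list_to_mat(obj$influence_rate),
                 production_rate = list_to_mat(obj$production_rate),
                 consumption_rate = list_to_mat(obj$consumption_rate),
                 saturation = list_to_mat(obj$saturation),
                 influence_link = list_to_mat(obj$influence_link, TRUE),
                 production_link = list_to_mat(obj$production_link, TRUE),
                 resource_K = obj$resource_K,
                 resource_consumption = obj$resource_consumption,
                 config = cfg, seed = as.integer(obj$seed)),
            class = "interaction_network")
}

#' Write / read an invader specification as JSON
#'
#' @param inv An `invader_spec`.
#' @param path File path.
#' @export
write_invader_json <- function(inv, path) {
  stopifnot(inherits(inv, "invader_spec"))
  obj <- c(list(schema_version = SCHEMA_VERSION, type = "invader_spec"),
           unclass(inv))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_invader_json
#' @export
read_invader_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "invader_spec"))
    stop("not a serialized invader")
  obj$schema_version <- NULL
  obj$type <- NULL
  obj$n_mediators <- as.integer(obj$n_mediators)
  obj$influence_link <- as.logical(obj$influence_link)
  obj$production_link <- as.logical(obj$production_link)
  structure(obj, class = "invader_spec")
}

#' Write / read an assembled resident community as JSON
#'
#' Bundles the parent network, the survivor list and the harvest state so
#' an assembly cohort can be reused across invasion experiments.
#'
#' @param rc A `resident_community`.
#' @param path File path.
#' @export
write_community_json <- function(rc, path) {
  stopifnot(inherits(rc, "resident_community"))
  nettmp <- tempfile(fileext = ".json")
  on.exit(unlink(nettmp))
  write_network_json(rc$network, nettmp)
  obj <- list(schema_version = SCHEMA_VERSION,
              type = "resident_community",
              network = jsonlite::read_json(nettmp, simplifyVector = FALSE),
              survivors = rc$survivors,
              species = rc$harvest_state$species,
              mediators = rc$harvest_state$mediators,
              resource = if (is.na(rc$harvest_state$resource)) NULL else
                rc$harvest_state$resource,
              time = rc$harvest_state$time,
              generations = rc$harvest_state$generations,
              fractions = rc$fractions,
              richness = rc$richness,
              model = rc$model,
              cycle_cfg = unclass(rc$cycle_cfg),
              rcfg = if (is.null(rc$rcfg)) NULL else unclass(rc$rcfg),
              collapsed = rc$collapsed, stalled = rc$stalled,
              n_cycles = rc$n_cycles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_community_json
#' @export
read_community_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "resident_community"))
    stop("not a serialized resident community")
  nettmp <- tempfile(fileext = ".json")
  on.exit(unlink(nettmp))
  jsonlite::write_json(obj$network, nettmp, auto_unbox = FALSE, digits = NA)
  net <- read_network_json(nettmp)
  cc <- obj$cycle_cfg
  cycle_cfg <- cycle_config(n_inoc = cc$n_inoc, n_dil = cc$n_dil,
                            n_ext = cc$n_ext,
                            target_generations = cc$target_generations,
                            timestep_divisor = cc$timestep_divisor,
                            max_cycle_time = cc$max_cycle_time,
                            stall_factor = cc$stall_factor,
                            max_cycles = cc$max_cycles)
  rcfg <- if (length(obj$rcfg) == 0) NULL else
    resource_config(R0 = obj$rcfg$R0, KR_range = obj$rcfg$KR_range,
                    alphaR_range = obj$rcfg$alphaR_range)
  state <- community_state(obj$species, obj$mediators,
                           resource = if (length(obj$resource) == 0)
                             NA_real_ else as.numeric(obj$resource),
                           time = obj$time, generations = obj$generations)
  structure(list(network = net,
                 survivors = as.integer(obj$survivors),
                 harvest_state = state,
                 fractions = obj$fractions,
                 richness = as.integer(obj$richness),
                 model = obj$model,
                 cycle_cfg = cycle_cfg,
                 rcfg = rcfg,
                 collapsed = obj$collapsed,
                 stalled = obj$stalled,
                 n_cycles = obj$n_cycles),
            class = "resident_community")
}

#' Write an outcome table (with its configuration snapshot) to CSV + JSON
#'
#' The table itself goes to `<path>` as CSV; the root seed, confidence
#' level and configuration snapshot go to `<path>.json`.
#'
#' @param x An `outcome_table`.
#' @param path CSV file path.
#' @export
write_outcome_table <- function(x, path) {
  stopifnot(inherits(x, "outcome_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(schema_version = SCHEMA_VERSION,
               seed = attr(x, "seed"), level = attr(x, "level"),
               model = attr(x, "model"),
               match_seeds = attr(x, "match_seeds"),
               config = unclass(attr(x, "config")),
               cycle_config = unclass(attr(x, "cycle_config")),
               resource_config = unclass(attr(x, "resource_config")),
               regenerations = attr(x, "regenerations"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
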