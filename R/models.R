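# Model registry: one uniform handle over the seven LSO models.

#' The seven LSO model identifiers
#' @return character vector of model ids.
#' @export
lso_model_ids <- function() {
  c("coincidence", "stein_exp", "stein_alpha",
    "if_passive", "if_active", "wc_original", "wc_adjusted")
}

#' Construct an LSO model handle
#'
#' Bundles a model id with its (default or overridden) parameter set and,
#' for conductance-based models, the synapse description, so tuning-curve
#' and protocol functions can be written once for all seven models.
#'
#' @param id one of [lso_model_ids()].
#' @param params optional parameter object of the matching class; defaults
#'   to the published calibrated set.
#' @param synapse optional [synaptic_params()] (conductance models only).
#' @return an object of class `lso_model`.
#' @export
lso_model <- function(id = lso_model_ids(), params = NULL, synapse = NULL) {
  id <- match.arg(id)
  params <- params %||% switch(id,
    coincidence = coincidence_params(),
    stein_exp = stein_params("exponential"),
    stein_alpha = stein_params("alpha"),
    if_passive = passive_if_params(),
    if_active = active_if_params(),
    wc_original = wang_colburn_params("original"),
    wc_adjusted = wang_colburn_params("adjusted")
  )
  synapse <- synapse %||% synaptic_params()
  structure(list(id = id, params = params, synapse = synapse,
                 conductance_based = id %in% c("if_passive", "if_active",
                                               "wc_original", "wc_adjusted")),
            class = "lso_model")
}

#' @export
print.lso_model <- function(x, ...) {
  cat("<lso_model>", x$id, "\n")
  invisible(x)
}

as_lso_model <- function(model) {
  if (inherits(model, "lso_model")) model else lso_model(model)
}

#' Run any LSO model on a spike ensemble
#'
#' Uniform front end over the seven models; extra arguments are forwarded to
#' the model-specific runner ([run_coincidence_counting()], [run_stein()],
#' [run_passive_if()], [run_active_if()], [run_wang_colburn()]).
#'
#' @param model an [lso_model()] or a model id string.
#' @param inputs spike tibble from [build_input_set()] or [make_fixture()].
#' @param dt integration step, ms.
#' @param ... forwarded to the specific runner.
#' @return an `lso_sim` object.
#' @export
run_lso_model <- function(model, inputs, dt = 0.002, ...) {
  model <- as_lso_model(model)
  switch(model$id,
    coincidence = run_coincidence_counting(inputs, model$params, ...),
    stein_exp = ,
    stein_alpha = run_stein(inputs, model$params, dt = dt, ...),
    if_passive = run_passive_if(inputs, model$params, model$synapse, dt = dt, ...),
    if_active = run_active_if(inputs, model$params, model$synapse, dt = dt, ...),
    wc_original = ,
    wc_adjusted = run_wang_colburn(inputs, model$params, model$synapse, dt = dt, ...)
  )
}

# --- membrane protocol primitives (conductance models only) ------------------

require_conductance <- function(model) {
  if (!model$conductance_based) {
    abort(paste0("model `", model$id,
                 "` is a shot-noise model: it has no physical membrane, so ",
                 "membrane characterization protocols do not apply"))
  }
}

# internal: run the bare membrane (no synaptic input) under an external
# current and return trace / final potential. `current` is a scalar (pA) or
# a vector aligned to stimulus onset. Spike generation is disabled for IF
# models; `na_enabled` controls the WC sodium conductance.
membrane_response <- function(model, current = 0, duration_ms = 300,
                              dt = 0.002, settle = 200, v0 = NULL,
                              record = FALSE, record_every = 1L,
                              na_enabled = TRUE, spikes_enabled = FALSE) {
  model <- as_lso_model(model)
  require_conductance(model)
  args <- list(inputs = NULL, params = model$params, synapse = model$synapse,
               dt = dt, duration = duration_ms / 1000, I_ext = current,
               record = record, record_every = record_every,
               settle = settle, v0 = v0)
  switch(model$id,
    if_passive = do.call(run_passive_if, c(args, list(spikes_enabled = spikes_enabled))),
    if_active = do.call(run_active_if, c(args, list(spikes_enabled = spikes_enabled))),
    wc_original = ,
    wc_adjusted = do.call(run_wang_colburn, c(args, list(na_enabled = na_enabled)))
  )
}

#' Resting potential of a conductance-based model
#'
#' Settles the membrane with no input and no external current and returns the
#' final potential.
#'
#' @param model an [lso_model()] or id (conductance-based).
#' @param t_settle settle time, ms.
#' @param dt integration step, ms.
#' @return resting potential, mV.
#' @export
resting_potential <- function(model, t_settle = 500, dt = 0.002) {
  membrane_response(model, current = 0, duration_ms = t_settle, dt = dt,
                    settle = 0)$v_end
}

#' Bias current clamping a membrane at a target potential
#'
#' Finds, by 1-D root finding on the settled potential, the constant DC
#' current for which the membrane settles at `V_clamp` (the paper-style
#' "clamp by an additional constant DC current"). The settled potential is
#' required to match the target to 0.01 mV.
#'
#' @inheritParams resting_potential
#' @param V_clamp target holding potential, mV.
#' @param na_enabled whether the WC sodium conductance is active during the
#'   clamp (disabled for the I-V protocol).
#' @param t_settle settle time used for each root-finding evaluation, ms;
#'   generous by default because the slow KLVA inactivation gate needs
#'   several hundred ms to equilibrate.
#' @return bias current, pA.
#' @export
find_clamp_bias <- function(model, V_clamp = -60, t_settle = 1500, dt = 0.002,
                            na_enabled = TRUE) {
  model <- as_lso_model(model)
  require_conductance(model)
  settled <- function(I) {
    membrane_response(model, current = I, duration_ms = t_settle, dt = dt,
                      settle = 0, v0 = V_clamp, na_enabled = na_enabled)$v_end
  }
  f <- function(I) settled(I) - V_clamp
  # the settled potential is increasing in I; start from a physiological
  # bracket and let uniroot extend it if needed
  root <- uniroot(f, c(-2000, 2000), extendInt = "upX", tol = 1e-4,
                  maxiter = 200)
  if (abs(root$f.root) > 0.01) {
    abort(sprintf("clamp root-finding did not reach |V - V_clamp| < 0.01 mV (residual %.4f mV)",
                  root$f.root))
  }
  root$root
}
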