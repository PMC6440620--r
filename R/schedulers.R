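#' Gaussian error function
#'
#' Computes \eqn{\mathrm{erf}(x) = \frac{2}{\sqrt{\pi}} \int_0^x e^{-t^2} dt},
#' evaluated through the normal CDF (`erf(x) = 2 pnorm(x sqrt(2)) - 1`), which
#' is accurate to machine precision. This is the primitive behind the Gauss
#' error learning-rate scheduler.
#'
#' @param x numeric vector of finite values.
#' @return numeric vector of the same length, values in (-1, 1).
#' @examples
#' erf_value(0)      # 0
#' erf_value(1)      # 0.8427008
#' @export
erf_value <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stopf("erf_value() requires finite numeric input")
  2 * pnorm(x * sqrt(2)) - 1
}

#' Learning-rate schedules
#'
#' Constructors for the per-epoch learning-rate schedules used to train the
#' networks in this package. All schedules are deterministic closed forms of
#' the (1-based) epoch index `e`:
#'
#' * `erf_schedule()`: the Gauss error (ERF) scheduler,
#'   \deqn{\varepsilon(e) = lr_{min} + \frac{lr_{max}-lr_{min}}{2}
#'     \left(1 - \mathrm{erf}\!\left(\frac{e(\beta-\alpha)}{E} + \alpha\right)\right),}
#'   a smooth three-phase decay: flat near `lr_max` while the erf argument is
#'   well below zero, a transition whose steepness is set by
#'   \eqn{|\alpha|/|\beta|}, and a flat tail near `lr_min`. `alpha` must be a
#'   negative and `beta` a positive integer; `lr_min` must be strictly
#'   positive so the rate never approaches zero.
#' * `step_schedule()`: piecewise-constant decay. The rate attached to a
#'   changepoint epoch applies from the *following* epoch onward ("divide
#'   after the 60th epoch" means epochs 61+ use the reduced rate).
#' * `step_r_schedule()`: a step schedule whose two drop epochs derive from a
#'   single ratio `R` via [step_r_breakpoints()]; the rate starts at
#'   `initial_rate` and is divided by 10 at each breakpoint.
#' * `cosine_schedule()`: half-cosine decay. The default `form = "additive"`
#'   uses amplitude \eqn{(lr_{max}+lr_{min})/2}; `form = "annealing"` uses the
#'   conventional \eqn{(lr_{max}-lr_{min})/2}. The two coincide at the
#'   default `lr_min = 0`.
#' * `exponential_schedule()`: \eqn{\varepsilon(e) = lr_0 \lambda^e}.
#'
#' @param lr_max,lr_min maximum and minimum learning rates.
#' @param alpha negative integer; controls how long training stays at
#'   `lr_max`.
#' @param beta positive integer; controls how long training stays at
#'   `lr_min`.
#' @param epochs total number of training epochs `E`.
#' @param initial_rate rate used before the first changepoint.
#' @param changepoints integer vector of strictly increasing epochs.
#' @param rates rates applied after each changepoint; strictly decreasing.
#' @param R ratio of the two drop epochs, in (0, 1).
#' @param divisor factor by which the rate is divided at each breakpoint.
#' @param form cosine amplitude convention, see above.
#' @param lr0 initial rate of the exponential schedule.
#' @param lambda discount factor in \[0, 1\].
#' @return an object of class `lr_schedule`; query it with [schedule_rate()]
#'   or [tabulate_schedule()].
#' @examples
#' s <- erf_schedule(lr_max = 0.1, lr_min = 1e-4, alpha = -3, beta = 3,
#'                   epochs = 300)
#' schedule_rate(s, 150)   # (lr_max + lr_min) / 2 by symmetry
#' @seealso [step_r_breakpoints()]
#' @export
erf_schedule <- function(lr_max, lr_min, alpha, beta, epochs) {
  lr_max <- check_number(lr_max, "lr_max", lower = 0, strict_lower = TRUE)
  lr_min <- check_number(lr_min, "lr_min", lower = 0, strict_lower = TRUE)
  if (lr_min >= lr_max) stopf("need 0 < lr_min < lr_max")
  alpha <- check_number(alpha, "alpha", upper = 0, strict_upper = TRUE, integer = TRUE)
  beta <- check_number(beta, "beta", lower = 0, strict_lower = TRUE, integer = TRUE)
  epochs <- check_number(epochs, "epochs", lower = 1, integer = TRUE)
  structure(list(lr_max = lr_max, lr_min = lr_min, alpha = alpha,
                 beta = beta, epochs = epochs),
            class = c("erf_schedule", "lr_schedule"))
}

#' @rdname erf_schedule
#' @export
step_schedule <- function(initial_rate, changepoints = integer(),
                          rates = numeric(), epochs = NULL) {
  initial_rate <- check_number(initial_rate, "initial_rate", lower = 0, strict_lower = TRUE)
  if (length(changepoints) != length(rates))
    stopf("'changepoints' and 'rates' must have equal length")
  if (length(changepoints)) {
    if (any(changepoints != round(changepoints)) || any(changepoints < 1))
      stopf("changepoint epochs must be positive integers")
    if (any(diff(changepoints) <= 0)) stopf("changepoint epochs must be strictly increasing")
    if (any(diff(c(initial_rate, rates)) >= 0)) stopf("rates must be strictly decreasing")
    if (!is.null(epochs) && any(changepoints >= epochs))
      stopf("changepoints must lie strictly inside (0, epochs)")
  }
  structure(list(initial_rate = initial_rate,
                 changepoints = as.integer(changepoints),
                 rates = as.numeric(rates), epochs = epochs),
            class = c("step_schedule", "lr_schedule"))
}

#' Drop epochs of the step-R schedule
#'
#' Derives the two learning-rate drop epochs from a single ratio `R`:
#' \eqn{E_2 = \lfloor E/(1+R) \rfloor} and \eqn{E_1 = \lfloor R E_2 \rfloor},
#' so that \eqn{E_1/E_2 \approx R}. With `R = 0.3` and 200 epochs this gives
#' the breakpoints (45, 153).
#'
#' @param R ratio in (0, 1).
#' @param epochs total number of epochs, at least 2.
#' @return integer vector `c(E1, E2)`.
#' @export
step_r_breakpoints <- function(R, epochs) {
  R <- check_number(R, "R", lower = 0, upper = 1, strict_lower = TRUE, strict_upper = TRUE)
  epochs <- check_number(epochs, "epochs", lower = 2, integer = TRUE)
  E2 <- floor(epochs / (1 + R))
  E1 <- floor(R * E2)
  if (E1 < 1 || E1 >= E2 || E2 >= epochs)
    stopf("degenerate breakpoints (E1=%d, E2=%d) for R=%g, epochs=%d",
          E1, E2, R, epochs)
  c(E1 = as.integer(E1), E2 = as.integer(E2))
}

#' @rdname erf_schedule
#' @export
step_r_schedule <- function(R, epochs, initial_rate = 0.1, divisor = 10) {
  bp <- step_r_breakpoints(R, epochs)
  s <- step_schedule(initial_rate, changepoints = bp,
                     rates = initial_rate / divisor^(1:2), epochs = epochs)
  s$R <- R
  s
}

#' @rdname erf_schedule
#' @export
cosine_schedule <- function(lr_max, lr_min = 0, epochs,
                            form = c("additive", "annealing")) {
  lr_max <- check_number(lr_max, "lr_max", lower = 0, strict_lower = TRUE)
  lr_min <- check_number(lr_min, "lr_min", lower = 0)
  if (lr_max <= lr_min) stopf("need lr_max > lr_min")
  epochs <- check_number(epochs, "epochs", lower = 1, integer = TRUE)
  structure(list(lr_max = lr_max, lr_min = lr_min, epochs = epochs,
                 form = match.arg(form)),
            class = c("cosine_schedule", "lr_schedule"))
}

#' @rdname erf_schedule
#' @export
exponential_schedule <- function(lr0, lambda) {
  lr0 <- check_number(lr0, "lr0", lower = 0, strict_lower = TRUE)
  lambda <- check_number(lambda, "lambda", lower = 0, upper = 1)
  structure(list(lr0 = lr0, lambda = lambda, epochs = NULL),
            class = c("exponential_schedule", "lr_schedule"))
}

#' Evaluate a schedule at an epoch
#'
#' @param schedule an `lr_schedule` object.
#' @param e epoch index (1-based); must lie in `[1, epochs]` for schedules
#'   with a fixed horizon.
#' @return the learning rate for epoch `e`.
#' @export
schedule_rate <- function(schedule, e) UseMethod("schedule_rate")

check_epoch <- function(e, epochs) {
  if (!is.numeric(e) || any(!is.finite(e)) || any(e != round(e)) || any(e < 1))
    stopf("epoch index must be a positive integer")
  if (!is.null(epochs) && any(e > epochs))
    stopf("epoch index must lie in (0, %d]", epochs)
  as.numeric(e)
}

#' @export
schedule_rate.erf_schedule <- function(schedule, e) {
  e <- check_epoch(e, schedule$epochs)
  p <- schedule
  arg <- e * (p$beta - p$alpha) / p$epochs + p$alpha
  p$lr_min + (p$lr_max - p$lr_min) / 2 * (1 - erf_value(arg))
}

#' @export
schedule_rate.step_schedule <- function(schedule, e) {
  e <- check_epoch(e, NULL)
  rates <- c(schedule$initial_rate, schedule$rates)
  # findInterval over changepoints: rate k+1 applies for e > changepoint k
  idx <- findInterval(e - 0.5, schedule$changepoints) + 1L
  rates[idx]
}

#' @export
schedule_rate.cosine_schedule <- function(schedule, e) {
  e <- check_epoch(e, schedule$epochs)
  p <- schedule
  amp <- if (p$form == "additive") (p$lr_max + p$lr_min) / 2 else (p$lr_max - p$lr_min) / 2
  p$lr_min + amp * (1 + cos(pi * e / p$epochs))
}

#' @export
schedule_rate.exponential_schedule <- function(schedule, e) {
  e <- check_epoch(e, NULL)
  schedule$lr0 * schedule$lambda^e
}

#' Tabulate a schedule over all epochs
#'
#' @param schedule an `lr_schedule` object.
#' @param epochs horizon; defaults to the schedule's own `epochs` field.
#' @return a `data.frame` with columns `epoch` and `learning_rate`.
#' @export
tabulate_schedule <- function(schedule, epochs = schedule$epochs) {
  if (is.null(epochs)) stopf("schedule has no horizon; supply 'epochs'")
  epochs <- check_number(epochs, "epochs", lower = 1, integer = TRUE)
  e <- seq_len(epochs)
  data.frame(epoch = e, learning_rate = schedule_rate(schedule, e))
}

#' @export
print.lr_schedule <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  fields <- x[!vapply(x, is.null, logical(1))]
  for (nm in names(fields))
    cat(sprintf("  %s: %s\n", nm, paste(format(fields[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Build a schedule from a flat configuration list
#'
#' Keys: `type` (one of `"erf"`, `"step"`, `"step_r"`, `"cosine"`,
#' `"exponential"`) plus the constructor arguments of the corresponding
#' schedule (`lr_max`, `lr_min`, `alpha`, `beta`, `epochs`, `initial_rate`,
#' `changepoints`, `rates`, `R`, `lr0`, `lambda`).
#'
#' @param config a named list, e.g. parsed from a JSON config file.
#' @return an `lr_schedule`.
#' @export
schedule_from_config <- function(config) {
  if (is.null(config$type)) stopf("scheduler config needs a 'type' key")
  take <- function(fn, keys) {
    args <- config[intersect(keys, names(config))]
    do.call(fn, args)
  }
  switch(config$type,
    erf = take(erf_schedule, c("lr_max", "lr_min", "alpha", "beta", "epochs")),
    step = take(step_schedule, c("initial_rate", "changepoints", "rates", "epochs")),
    step_r = take(step_r_schedule, c("R", "epochs", "initial_rate", "divisor")),
    cosine = take(cosine_schedule, c("lr_max", "lr_min", "epochs", "form")),
    exponential = take(exponential_schedule, c("lr0", "lambda")),
    stopf("unknown scheduler type '%s'", config$type))
}
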