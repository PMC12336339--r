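#' Packaged generator calibration constants
#'
#' The frozen output of [calibrate_generator()] run at its defaults
#' (moment-matching pilot of n = 100,000); consumed by [default_config()].
#' Re-running the calibration routine reproduces these values up to pilot
#' Monte-Carlo error.
#'
#' @return An object of class `sr_calibration`.
#' @export
srscore_calibration <- function() {
  structure(list(support = list(thresholds = c(-2.23627256591277, -0.994803523611657, 
  0.24666551868946)), trust = list(thresholds = c(-1.80061818916204, 
  -0.783124379331173, 0.234369430499694, 1.25186324033056)), phq9 = list(
      rho = 0.556644258734225, thresholds = c(-0.318382966857132, 
      1.24429752688896, 1.39429752689257)), ghq12 = list(rho = 0.365232149809765, 
      thresholds = c(-1.06253715009951, 0.309268399039388, 1.3492821018963
      )), rec = list(rho = 0.434826253229139, thresholds = c(-1.56799874688461, 
  -0.690656695030305, 0.21805813192744, 1.42240517340337)), exposure = list(
      lambda = 0.247412317556581, tau = c(0.279319034447454, 0.412463129441405, 
      0.524400512708041)), struct = list(beta1 = list(dep = 0.17566856443385, 
      dis = 0.169917284203413), beta2 = list(dep = 0, dis = 0), 
      k2 = list(dep = 1.21853160480832, dis = 1.167921129264), 
      k_rec = 1.56274740527814, core_center = list(dep = 0.0060172308972063, 
          dis = 0.00916515586155365), core_scale = list(dep = 1.19738792617468, 
          dis = 1.17504104651392), rec_center = -0.000667701851062788, 
      rec_scale = 1.00471007998925, resid_skew = 0.95, distress_share = 0.793421231714005, 
      rf_center = c(support = 3.23, trust = 2.26, rec = 3.19), 
      e_center = 39, path_gain = list(b = list(dep = 0.955032778279096, 
          dis = 0.947612457321059), c = list(dep = 1.04329455442495, 
          dis = 0.963646379776091), mod = list(dep = 1.17336831994887, 
          dis = 1.00910566903427), cum = list(dep = 1.03718112447656, 
          dis = 0.997777655228749))), targets = list(exposure = list(
      mean = c(39, 34, 30), sd = 15), phq9 = list(mean = 7.3, sd = 5.4, 
      alpha = 0.88, tail = 0.27), ghq12 = list(mean = 15.8, sd = 6.1, 
      alpha = 0.85), rec = list(mean = 3.19, sd = 0.72, alpha = 0.8), 
      support = list(mean = 3.23, sd = 0.74), trust = list(mean = 2.26, 
          sd = 0.99), r_e_phq = 0.37, r_e_ghq = 0.33, r_sr = 0.68)), class = "sr_calibration")
}
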