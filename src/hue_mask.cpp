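#include <Rcpp.h>
using namespace Rcpp;

// Binary hue mask of an RGB frame array (rows x cols x 3, values in [0,1]):
// TRUE where saturation >= sat_min and the circular hue distance to the
// target does not exceed thr. Single fused pass over the pixels; equals the
// composition binarize_hue(hue_similarity_image(frame, target, sat_min)).
// [[Rcpp::export(name = ".hue_mask_cpp")]]
LogicalMatrix hue_mask_cpp(NumericVector frame, double target, double sat_min,
                           double thr) {
  IntegerVector dim = frame.attr("dim");
  if (dim.size() != 3 || dim[2] < 3)
    stop("hue_mask: frame must be a rows x cols x 3 array");
  const int n = dim[0] * dim[1];
  const double *r = frame.begin();
  const double *g = r + n;
  const double *b = g + n;
  LogicalMatrix out(dim[0], dim[1]);
  for (int i = 0; i < n; ++i) {
    double mx = r[i] > g[i] ? r[i] : g[i];
    if (b[i] > mx) mx = b[i];
    double mn = r[i] < g[i] ? r[i] : g[i];
    if (b[i] < mn) mn = b[i];
    double rng = mx - mn;
    if (mx <= 0.0 || rng <= 0.0 || rng / mx < sat_min) continue;
    double h;
    if (mx == r[i])
      h = (g[i] - b[i]) / rng;
    else if (mx == g[i])
      h = (b[i] - r[i]) / rng + 2.0;
    else
      h = (r[i] - g[i]) / rng + 4.0;
    h /= 6.0;
    if (h < 0.0) h += 1.0;
    double d = h - target;
    if (d < 0.0) d = -d;
    if (d > 0.5) d = 1.0 - d;
    out[i] = d <= thr;
  }
  return out;
}
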