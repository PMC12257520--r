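#ifndef PIMDWATER_CORE_H
#define PIMDWATER_CORE_H

#include <Rcpp.h>

struct FFParams {
  double Dr, ar, req;
  double ktheta, thetaeq;
  double eps, sigma;
  double qH, qM;
  double gammaM;
  double rc, epsrf;
  bool shift_rf;
  double krf, crf;
};

FFParams parse_ff(const Rcpp::List &ff);

Rcpp::List water_eval(const double *x, int nmol, int nsite, int nb, double L,
                      const FFParams &p, bool intra, bool inter);

#endif
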