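// Whole-body PBPK-PD core: compiled right-hand side of the ODE system and a
// stiff Rosenbrock 4(3) integrator (Kaps-Rentrop, Shampine coefficient set).
//
// State layout (0-based; mirrored by state_labels() on the R side):
//   0            SC depot                       [nmol]
//   1, 2         venous / arterial plasma       [nmol]
//   3 + 3*i + 0  organ i vascular               [nmol]
//   3 + 3*i + 1  organ i interstitial           [nmol]   (liver slot unused)
//   3 + 3*i + 2  organ i endothelial endosomes  [nmol]   (liver slot unused)
//   48..55       liver TMDD block: D_int, A_free, DA, DA_endo, A_endo,
//                D_endo, D_cyt, C_RISC (all amounts, nmol; receptors nmol)
//   56, 57       mRNA, Protein                  [%]
//   58, 59       cumulative urine / degraded    [nmol]
//
// Units: amounts nmol, volumes L, flows L/h, time h. All transfers are booked
// as a single flux added with opposite signs to exactly two states (plus the
// explicit sinks), so total drug is a linear invariant of the RHS; the
// Rosenbrock stages preserve linear invariants to rounding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ModelParams {
  int n_org, iliver, ikidney, ilung;
  arma::vec Vvas, Vint, Vendo, Q, Jlymph, convL, convS, diffL, diffS,
      kup, krec, kdeg_tis, kdeg_vas, Qout;
  arma::ivec dest;  // 0 = venous, 1 = arterial, 2 = liver vascular
  double Vven, Vart, Qco, fu, Kp, ka, GFR, PSA_liver, kdeg_plasma;
  double kon, koff, kint, kcle, krecR, kdegR, kdegA, ksyn_amt;
  double kendo, fesc, kdegC, konR, koffR, kDR, RISCtot_nM;
  double Vint_liv, Vcell_liv, Vliv_total;
  double Smax, SC50, gamma, kdegm, kdegp, mRNA0, Prot0;
};

ModelParams unpack(const List& P) {
  ModelParams p;
  p.n_org = as<int>(P["n_org"]);
  p.iliver = as<int>(P["iliver"]);
  p.ikidney = as<int>(P["ikidney"]);
  p.ilung = as<int>(P["ilung"]);
  p.Vvas = as<arma::vec>(P["Vvas"]);
  p.Vint = as<arma::vec>(P["Vint"]);
  p.Vendo = as<arma::vec>(P["Vendo"]);
  p.Q = as<arma::vec>(P["Q"]);
  p.Jlymph = as<arma::vec>(P["Jlymph"]);
  p.convL = as<arma::vec>(P["convL"]);
  p.convS = as<arma::vec>(P["convS"]);
  p.diffL = as<arma::vec>(P["diffL"]);
  p.diffS = as<arma::vec>(P["diffS"]);
  p.kup = as<arma::vec>(P["kup"]);
  p.krec = as<arma::vec>(P["krec"]);
  p.kdeg_tis = as<arma::vec>(P["kdeg_tis"]);
  p.kdeg_vas = as<arma::vec>(P["kdeg_vas"]);
  p.Qout = as<arma::vec>(P["Qout"]);
  p.dest = as<arma::ivec>(P["dest"]);
  p.Vven = as<double>(P["Vven"]);
  p.Vart = as<double>(P["Vart"]);
  p.Qco = as<double>(P["Qco"]);
  p.fu = as<double>(P["fu"]);
  p.Kp = as<double>(P["Kp"]);
  p.ka = as<double>(P["ka"]);
  p.GFR = as<double>(P["GFR"]);
  p.PSA_liver = as<double>(P["PSA_liver"]);
  p.kdeg_plasma = as<double>(P["kdeg_plasma"]);
  p.kon = as<double>(P["kon"]);
  p.koff = as<double>(P["koff"]);
  p.kint = as<double>(P["kint"]);
  p.kcle = as<double>(P["kcle"]);
  p.krecR = as<double>(P["krecR"]);
  p.kdegR = as<double>(P["kdegR"]);
  p.kdegA = as<double>(P["kdegA"]);
  p.ksyn_amt = as<double>(P["ksyn_amt"]);
  p.kendo = as<double>(P["kendo"]);
  p.fesc = as<double>(P["fesc"]);
  p.kdegC = as<double>(P["kdegC"]);
  p.konR = as<double>(P["konR"]);
  p.koffR = as<double>(P["koffR"]);
  p.kDR = as<double>(P["kDR"]);
  p.RISCtot_nM = as<double>(P["RISCtot_nM"]);
  p.Vint_liv = as<double>(P["Vint_liv"]);
  p.Vcell_liv = as<double>(P["Vcell_liv"]);
  p.Vliv_total = as<double>(P["Vliv_total"]);
  p.Smax = as<double>(P["Smax"]);
  p.SC50 = as<double>(P["SC50"]);
  p.gamma = as<double>(P["gamma"]);
  p.kdegm = as<double>(P["kdegm"]);
  p.kdegp = as<double>(P["kdegp"]);
  p.mRNA0 = as<double>(P["mRNA0"]);
  p.Prot0 = as<double>(P["Prot0"]);
  return p;
}

const int IDEPOT = 0, IVEN = 1, IART = 2;
inline int ivas(int i) { return 3 + 3 * i; }
inline int iint(int i) { return 3 + 3 * i + 1; }
inline int iendo(int i) { return 3 + 3 * i + 2; }

void rhs(const arma::vec& y, arma::vec& dy, const ModelParams& p) {
  const int nliv = 3 + 3 * p.n_org;  // start of liver block
  const int IDint = nliv, IAfree = nliv + 1, IDA = nliv + 2,
            IDAe = nliv + 3, IAendo = nliv + 4, IDendo = nliv + 5,
            IDcyt = nliv + 6, IRISC = nliv + 7;
  const int ImRNA = nliv + 8, IProt = nliv + 9, IUrine = nliv + 10,
            IDegr = nliv + 11;
  dy.zeros();

  const double Cven = y(IVEN) / p.Vven;
  const double Cart = y(IART) / p.Vart;

  // SC depot -> venous plasma
  const double abs_in = p.ka * y(IDEPOT);
  dy(IDEPOT) -= abs_in;
  dy(IVEN) += abs_in;

  for (int i = 0; i < p.n_org; ++i) {
    const int vi = ivas(i), ii = iint(i), ei = iendo(i);
    const bool liver = (i == p.iliver);
    const double Cvas = y(vi) / p.Vvas(i);
    const double Cint = liver ? y(IDint) / p.Vint_liv : y(ii) / p.Vint(i);
    const int int_state = liver ? IDint : ii;

    // two-pore exchange (Peclet factors folded into diff* at assembly)
    const double grad = Cvas - Cint / p.Kp;
    const double f2p = p.fu * ((p.convL(i) + p.convS(i)) * Cvas +
                               (p.diffL(i) + p.diffS(i)) * grad);
    dy(vi) -= f2p;
    dy(int_state) += f2p;

    if (liver && p.PSA_liver > 0) {
      const double fp = p.fu * p.PSA_liver * (Cvas - Cint / p.Kp);
      dy(vi) -= fp;
      dy(IDint) += fp;
    }

    // lymph return interstitial -> venous
    const double lym = p.Jlymph(i) * Cint;
    dy(int_state) -= lym;
    dy(IVEN) += lym;

    // plasma inflow (lung from venous pool, others from arterial)
    if (i == p.ilung) {
      const double infl = p.Qco * Cven;
      dy(IVEN) -= infl;
      dy(vi) += infl;
    } else {
      const double infl = p.Q(i) * Cart;  // liver row = hepatic artery
      dy(IART) -= infl;
      dy(vi) += infl;
    }

    // plasma outflow to destination pool
    const double out = p.Qout(i) * Cvas;
    dy(vi) -= out;
    if (p.dest(i) == 0) dy(IVEN) += out;
    else if (p.dest(i) == 1) dy(IART) += out;
    else dy(ivas(p.iliver)) += out;  // portal organs feed the liver

    if (!liver) {
      // unspecific endosomal trafficking
      const double up = p.kup(i) * y(ii);
      const double rec = p.krec(i) * y(ei);
      dy(ii) += rec - up;
      dy(ei) += up - rec;
      // RNase degradation in vascular, interstitial, endosomal
      const double dv = p.kdeg_vas(i) * y(vi);
      const double di = p.kdeg_tis(i) * y(ii);
      const double de = p.kdeg_tis(i) * y(ei);
      dy(vi) -= dv;
      dy(ii) -= di;
      dy(ei) -= de;
      dy(IDegr) += dv + di + de;
    }

    if (i == p.ikidney) {
      const double fil = p.fu * p.GFR * Cvas;
      dy(vi) -= fil;
      dy(IUrine) += fil;
    }
  }

  // plasma pool degradation
  const double dven = p.kdeg_plasma * y(IVEN);
  const double dart = p.kdeg_plasma * y(IART);
  dy(IVEN) -= dven;
  dy(IART) -= dart;
  dy(IDegr) += dven + dart;

  // ---- liver ASGPR TMDD ----
  const double CD = y(IDint) / p.Vint_liv;
  const double CA = y(IAfree) / p.Vint_liv;
  const double bind = p.kon * CD * CA * p.Vint_liv;
  const double unbind = p.koff * y(IDA);
  const double internal = p.kint * y(IDA);
  const double cle = p.kcle * y(IDAe);
  const double exit = p.kendo * y(IDendo);
  const double dcyt_deg = p.kdegC * y(IDcyt);

  dy(IDint) += unbind - bind;
  dy(IAfree) += p.ksyn_amt - p.kdegA * y(IAfree) - bind + unbind +
                p.krecR * y(IAendo);
  dy(IDA) += bind - unbind - internal;
  dy(IDAe) += internal - cle;
  dy(IAendo) += cle - (p.krecR + p.kdegR) * y(IAendo);
  dy(IDendo) += cle - exit;
  dy(IDcyt) += p.fesc * exit - dcyt_deg;
  dy(IDegr) += (1.0 - p.fesc) * exit + dcyt_deg;

  // ---- RISC loading (hepatocyte intracellular volume basis) ----
  const double Ccyt = y(IDcyt) / p.Vcell_liv;
  const double CR = y(IRISC) / p.Vcell_liv;
  const double on = p.konR * Ccyt * (p.RISCtot_nM - CR) * p.Vcell_liv;
  const double off = p.koffR * y(IRISC);
  const double risc_deg = p.kDR * y(IRISC);
  dy(IDcyt) += off - on;
  dy(IRISC) += on - off - risc_deg;
  dy(IDegr) += risc_deg;

  // ---- pharmacodynamics (liver tissue basis RISC) ----
  const double Crisc_tis = y(IRISC) / p.Vliv_total;
  const double stim =
      1.0 + p.Smax * Crisc_tis / (p.SC50 + Crisc_tis);
  dy(ImRNA) += p.kdegm * p.mRNA0 - stim * p.kdegm * y(ImRNA);
  double rel = y(ImRNA) / p.mRNA0;
  if (rel < 0) rel = 0;
  dy(IProt) += p.kdegp * (p.Prot0 * std::pow(rel, p.gamma) - y(IProt));
}

void jacobian_fd(const arma::vec& y, const arma::vec& f0, arma::mat& J,
                 const ModelParams& p) {
  const int n = y.n_elem;
  arma::vec yp = y, fp(n);
  const double sqeps = std::sqrt(std::numeric_limits<double>::epsilon());
  for (int j = 0; j < n; ++j) {
    const double dj = sqeps * std::max(std::abs(y(j)), 1e-6);
    yp(j) = y(j) + dj;
    rhs(yp, fp, p);
    J.col(j) = (fp - f0) / dj;
    yp(j) = y(j);
  }
}

}  // namespace

//' @rdname model_rhs
//' @keywords internal
// [[Rcpp::export(name = ".cpp_rhs")]]
NumericVector cpp_rhs(NumericVector y, List par) {
  ModelParams p = unpack(par);
  arma::vec yy(y.begin(), y.size(), false);
  arma::vec dy(y.size());
  rhs(yy, dy, p);
  return wrap(dy);
}

// Kaps-Rentrop 4(3) coefficients, Shampine parameter set.
static const double GAM = 0.5;
static const double A21 = 2.0, A31 = 48.0 / 25.0, A32 = 6.0 / 25.0;
static const double C21 = -8.0, C31 = 372.0 / 25.0, C32 = 12.0 / 5.0;
static const double C41 = -112.0 / 125.0, C42 = -54.0 / 125.0,
                    C43 = -2.0 / 5.0;
static const double B1 = 19.0 / 9.0, B2 = 0.5, B3 = 25.0 / 108.0,
                    B4 = 125.0 / 108.0;
static const double E1 = 17.0 / 54.0, E2 = 7.0 / 36.0, E3 = 0.0,
                    E4 = 125.0 / 108.0;

// [[Rcpp::export(name = ".cpp_integrate")]]
NumericMatrix cpp_integrate(NumericVector y0, NumericVector times, List par,
                            double rtol = 1e-8, double atol = 1e-10,
                            double hmax = 10.0) {
  ModelParams p = unpack(par);
  const int n = y0.size(), nt = times.size();
  arma::vec y(y0.begin(), n);
  NumericMatrix out(nt, n);
  for (int j = 0; j < n; ++j) out(0, j) = y(j);

  arma::mat J(n, n), A(n, n);
  arma::vec f0(n), f1(n), g1(n), g2(n), g3(n), g4(n), ytmp(n), ynew(n),
      err(n);
  const arma::mat I = arma::eye(n, n);

  double t = times[0];
  double h = 1e-5;
  long nstep = 0;
  const long max_steps = 20000000L;

  for (int k = 1; k < nt; ++k) {
    const double target = times[k];
    while (t < target) {
      if (++nstep > max_steps) {
        stop("integration exceeded step budget at t = %f", t);
      }
      if (h > hmax) h = hmax;
      if (t + h > target) h = target - t;
      rhs(y, f0, p);
      if (!f0.is_finite()) stop("non-finite derivatives at t = %f", t);
      jacobian_fd(y, f0, J, p);

      bool accepted = false;
      while (!accepted) {
        A = I / (GAM * h) - J;
        auto slv = [&](const arma::vec& b) {
          arma::vec x;
          if (!arma::solve(x, A, b, arma::solve_opts::fast)) {
            x.reset();
          }
          return x;
        };
        g1 = slv(f0);
        if (g1.n_elem == 0) {
          h *= 0.5;
          if (h < 1e-14) stop("singular iteration matrix at t = %f", t);
          continue;
        }
        ytmp = y + A21 * g1;
        rhs(ytmp, f1, p);
        g2 = slv(f1 + (C21 / h) * g1);
        ytmp = y + A31 * g1 + A32 * g2;
        rhs(ytmp, f1, p);
        g3 = slv(f1 + (C31 * g1 + C32 * g2) / h);
        // 4th stage reuses the 3rd stage argument
        g4 = slv(f1 + (C41 * g1 + C42 * g2 + C43 * g3) / h);

        ynew = y + B1 * g1 + B2 * g2 + B3 * g3 + B4 * g4;
        err = E1 * g1 + E2 * g2 + E3 * g3 + E4 * g4;

        double errmax = 0.0;
        for (int j = 0; j < n; ++j) {
          const double sc =
              atol + rtol * std::max(std::abs(y(j)), std::abs(ynew(j)));
          errmax = std::max(errmax, std::abs(err(j)) / sc);
        }
        if (!ynew.is_finite() || !std::isfinite(errmax)) {
          h *= 0.25;
          if (h < 1e-14) stop("step size underflow at t = %f", t);
          continue;
        }
        if (errmax <= 1.0) {
          t += h;
          y = ynew;
          const double fac =
              std::min(5.0, std::max(0.2, 0.9 * std::pow(std::max(errmax, 1e-12), -0.25)));
          h *= fac;
          accepted = true;
        } else {
          const double fac =
              std::max(0.1, 0.9 * std::pow(errmax, -1.0 / 3.0));
          h *= fac;
          if (h < 1e-14) stop("step size underflow at t = %f", t);
        }
      }
    }
    for (int j = 0; j < n; ++j) out(k, j) = y(j);
  }
  return out;
}
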