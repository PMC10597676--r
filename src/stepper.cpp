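// Inner time loop of the community simulation.
//
// The R side precomputes, per predator group: the feeding-kernel matrix
// Phi (group bins x full grid), the search-rate vector V, the senescence
// mortality vector, the interaction-coefficient row (towards each dynamic
// group and the static phytoplankton spectrum), and the recruitment rule.
// Each step then reduces to a handful of small dense matrix-vector
// products plus the explicit finite-difference update, which keeps
// millennial weekly-step runs to seconds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List css_run(List groups, arma::vec phyto, arma::vec w, arma::vec dw,
             List N0, double dt, int n_years, int steps_per_year,
             int avg_years, CharacterVector group_names) {
  const int G = groups.size();
  const arma::uword nb = w.n_elem;
  const arma::vec wdw = w % dw;
  const arma::vec w2dw = w % w % dw;

  std::vector<arma::uword> start(G);
  std::vector<arma::mat> Phi(G), PhiT(G);
  std::vector<arma::vec> V(G), sen(G), theta(G);
  std::vector<double> K(G), recruit(G);
  std::vector<int> src_type(G); // 0 = phytoplankton, 1 = zooplankton
  int zoo = -1;

  for (int i = 0; i < G; ++i) {
    List gi = groups[i];
    start[i] = as<int>(gi["start"]);
    Phi[i] = as<arma::mat>(gi["Phi"]);
    PhiT[i] = Phi[i].t();
    V[i] = as<arma::vec>(gi["V"]);
    sen[i] = as<arma::vec>(gi["sen"]);
    theta[i] = as<arma::vec>(gi["theta"]); // length G + 1, last = phyto
    K[i] = as<double>(gi["K"]);
    recruit[i] = as<double>(gi["recruit"]);
    src_type[i] = as<int>(gi["src_type"]);
    if (as<bool>(gi["is_zoo"])) zoo = i;
  }

  std::vector<arma::vec> N(G), dwm(G), wm(G);
  for (int i = 0; i < G; ++i) {
    arma::vec full = as<arma::vec>(N0[i]);
    const arma::uword ni = V[i].n_elem;
    N[i] = full.subvec(start[i], start[i] + ni - 1);
    dwm[i] = dw.subvec(start[i], start[i] + ni - 1);
    wm[i] = w.subvec(start[i], start[i] + ni - 1);
  }

  arma::mat biomass(n_years, G, arma::fill::zeros);
  std::vector<arma::vec> meanN(G);
  for (int i = 0; i < G; ++i) meanN[i] = arma::vec(V[i].n_elem,
                                                   arma::fill::zeros);
  int n_avg = 0;
  double clipped_total = 0.0, cfl_max = 0.0;

  std::vector<arma::vec> g(G), f(G), mu(G), Nnew(G);
  arma::vec field1(nb), field2(nb), mup(nb);

  for (int year = 0; year < n_years; ++year) {
    for (int s = 0; s < steps_per_year; ++s) {
      // rates from the synchronous current state
      mup.zeros();
      std::vector<arma::vec> q(G);
      for (int i = 0; i < G; ++i) {
        field1 = theta[i](G) * phyto;
        field2 = theta[i](G) * theta[i](G) * phyto;
        for (int j = 0; j < G; ++j) {
          if (theta[i](j) == 0.0) continue;
          arma::vec full(nb, arma::fill::zeros);
          full.subvec(start[j], start[j] + N[j].n_elem - 1) = N[j];
          field1 += theta[i](j) * full;
          field2 += theta[i](j) * theta[i](j) * full;
        }
        arma::vec D = Phi[i] * (wdw % field1);
        arma::vec M2 = Phi[i] * (w2dw % field2);
        g[i] = K[i] * (V[i] % D);
        f[i] = (K[i] * K[i]) * (V[i] % M2);
        q[i] = PhiT[i] * (V[i] % dwm[i] % N[i]);
      }
      for (int j = 0; j < G; ++j) {
        mu[j] = sen[j];
        for (int i = 0; i < G; ++i) {
          if (theta[i](j) == 0.0) continue;
          mu[j] += theta[i](j) *
            q[i].subvec(start[j], start[j] + N[j].n_elem - 1);
        }
      }
      // explicit update: upwind advection, central diffusion,
      // exact exponential mortality, clip
      for (int i = 0; i < G; ++i) {
        const arma::uword ni = N[i].n_elem;
        arma::vec flux = g[i] % N[i];
        double cfl = arma::max(g[i] * dt / dwm[i]);
        if (cfl > cfl_max) cfl_max = cfl;
        if (cfl > 1.0) {
          stop("CFL violation in group '%s' at year %d (max g*dt/dw = "
               "%.3f > 1); reduce dt",
               std::string(group_names[i]).c_str(), year + 1, cfl);
        }
        arma::vec upd = N[i];
        arma::vec FF = f[i] % N[i];
        for (arma::uword k = 0; k < ni; ++k) {
          double adv = ((k > 0 ? flux(k - 1) : 0.0) - flux(k)) / dwm[i](k);
          double dif = 0.0;
          if (k > 0 && k + 1 < ni) {
            double hm = wm[i](k) - wm[i](k - 1);
            double hp = wm[i](k + 1) - wm[i](k);
            dif = (hm * FF(k + 1) - (hm + hp) * FF(k) + hp * FF(k - 1)) /
              (hm * hp * (hm + hp));
          }
          upd(k) = (N[i](k) + dt * (adv + dif)) * std::exp(-mu[i](k) * dt);
        }
        for (arma::uword k = 0; k < ni; ++k) {
          if (upd(k) < 0.0) {
            clipped_total += -upd(k) * wm[i](k) * dwm[i](k);
            upd(k) = 0.0;
          }
          if (!std::isfinite(upd(k))) {
            stop("non-finite density in group '%s' at year %d",
                 std::string(group_names[i]).c_str(), year + 1);
          }
        }
        Nnew[i] = upd;
      }
      for (int i = 0; i < G; ++i) N[i] = Nnew[i];
      // constant-recruitment boundary (uses the updated zooplankton)
      for (int i = 0; i < G; ++i) {
        double src;
        if (src_type[i] == 0 || zoo < 0) {
          src = phyto(start[i]);
        } else {
          arma::uword pos = start[i] - start[zoo];
          src = N[zoo](pos);
        }
        N[i](0) = recruit[i] * src;
      }
    }
    for (int i = 0; i < G; ++i) {
      biomass(year, i) = arma::dot(wm[i] % dwm[i], N[i]);
    }
    if (year >= n_years - avg_years) {
      for (int i = 0; i < G; ++i) meanN[i] += N[i];
      ++n_avg;
    }
  }

  List meanN_out(G), finalN_out(G);
  for (int i = 0; i < G; ++i) {
    arma::vec mfull(nb, arma::fill::zeros), ffull(nb, arma::fill::zeros);
    if (n_avg > 0) {
      mfull.subvec(start[i], start[i] + N[i].n_elem - 1) = meanN[i] / n_avg;
    }
    ffull.subvec(start[i], start[i] + N[i].n_elem - 1) = N[i];
    meanN_out[i] = mfull;
    finalN_out[i] = ffull;
  }
  meanN_out.names() = group_names;
  finalN_out.names() = group_names;

  return List::create(_["annual_biomass"] = biomass,
                      _["mean_N"] = meanN_out,
                      _["final_N"] = finalN_out,
                      _["clipped_biomass"] = clipped_total,
                      _["cfl_max"] = cfl_max,
                      _["n_avg_snapshots"] = n_avg);
}
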