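{
  "schema": "pyloricnet/circuit-db/1",
  "meta": {
    "note": "Certified fixture circuits. Archetype circuits were found by seeded microbial-GA runs (see recipe) and certified by grid scans of the theta_LP/theta_PD plane at the stated step; certifications are re-verified by the package test suite.",
    "generator": "scripts in scratch/ reproduce via evolve_circuits(ga_config(pop_size, generations, seed))"
  },
  "circuits": [
    {
      "tau_LP": 1,
      "tau_PY": 1,
      "tau_PD": 1,
      "theta_LP": 0,
      "theta_PY": 0,
      "theta_PD": 0,
      "w_LP_to_LP": 0,
      "w_LP_to_PY": 0,
      "w_LP_to_PD": 0,
      "w_PY_to_LP": 0,
      "w_PY_to_PY": 0,
      "w_PY_to_PD": 0,
      "w_PD_to_LP": 0,
      "w_PD_to_PY": 0,
      "w_PD_to_PD": 0,
      "provenance": {
        "id": "zero-weight",
        "certified": {
          "pyloric": false,
          "analytic": true
        },
        "recipe": {
          "construction": "analytic: all weights zero, tau = 1, theta = 0"
        }
      }
    },
    {
      "tau_LP": 0.765144813265527,
      "tau_PY": 1.15713667662525,
      "tau_PD": 0.611315370177207,
      "theta_LP": 0.439630911790761,
      "theta_PY": -5.48259969609023,
      "theta_PD": -5.24966806337102,
      "w_LP_to_LP": 7.16026018867963,
      "w_LP_to_PY": 5.77647729918655,
      "w_LP_to_PD": -15.795458373896,
      "w_PY_to_LP": -15.2182789906589,
      "w_PY_to_PY": 12.7922735729,
      "w_PY_to_PD": 14.2804555321806,
      "w_PD_to_LP": -10.3555776492592,
      "w_PD_to_PY": -13.2409697412026,
      "w_PD_to_PD": 1.11468330784617,
      "provenance": {
        "id": "fully-regulatable",
        "certified": {
          "pyloric": true,
          "verdict": "fully-regulatable",
          "scan_step": 0.5,
          "min_tau": 0.6113
        },
        "recipe": {
          "method": "microbial GA, base-fitness mode",
          "seed": 4,
          "pop_size": 100,
          "generations": 100
        }
      }
    },
    {
      "tau_LP": 1.00287011738703,
      "tau_PY": 1.84563981768155,
      "tau_PD": 0.166053467472945,
      "theta_LP": -0.718675800282174,
      "theta_PY": -15.8043764270866,
      "theta_PD": 10.8911611868458,
      "w_LP_to_LP": 14.3949308411245,
      "w_LP_to_PY": 13.2603720139818,
      "w_LP_to_PD": -15.5075380273299,
      "w_PY_to_LP": -15.1272360556117,
      "w_PY_to_PY": 10.6100588397261,
      "w_PY_to_PD": -3.54839752184545,
      "w_PD_to_LP": 9.98061663452949,
      "w_PD_to_PY": -15.6923555858398,
      "w_PD_to_PD": -12.0789536888238,
      "provenance": {
        "id": "partially-regulatable",
        "certified": {
          "pyloric": true,
          "verdict": "partially-regulatable",
          "scan_step": 0.5,
          "min_tau": 0.1661,
          "target_3d": "0.5,0.55,0.31"
        },
        "recipe": {
          "method": "microbial GA, base-fitness mode",
          "seed": 23,
          "pop_size": 100,
          "generations": 100
        }
      }
    },
    {
      "tau_LP": 1.21482292211825,
      "tau_PY": 1.27377362385673,
      "tau_PD": 1.09379210332657,
      "theta_LP": 6.17656314644552,
      "theta_PY": -11.7462211879612,
      "theta_PD": -2.34816481666568,
      "w_LP_to_LP": -5.1909135940792,
      "w_LP_to_PY": 10.2161910989066,
      "w_LP_to_PD": 15.0119483176182,
      "w_PY_to_LP": -15.9591106423939,
      "w_PY_to_PY": 7.44340982780109,
      "w_PY_to_PD": 2.09811909442699,
      "w_PD_to_LP": 3.83741476375818,
      "w_PD_to_PY": 14.6234347932964,
      "w_PD_to_PD": -9.01348086138159,
      "provenance": {
        "id": "unregulatable",
        "certified": {
          "pyloric": true,
          "verdict": "unregulatable",
          "scan_step": 0.5,
          "min_tau": 1.0938
        },
        "recipe": {
          "method": "microbial GA, base-fitness mode",
          "seed": 5,
          "pop_size": 100,
          "generations": 100
        }
      }
    }
  ]
}
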