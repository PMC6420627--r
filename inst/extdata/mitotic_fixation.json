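{"version":1,"name":"mitotic fixation and staining","chamber":{"working_volume":1000,"residual_floor":100,"tubing_dead_volume":50},"steps":[{"kind":"AWAIT_EVENT","reagent":"","repeat_n":1,"message":"","delay":15},{"kind":"NOTIFY","reagent":"","repeat_n":1,"message":"fixation starting","delay":15},{"kind":"EXTRACT","reagent":"","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"INFUSE","pump":0,"reagent":"PFA 4% in PEM","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"WAIT","reagent":"","duration":15,"repeat_n":1,"message":"","delay":15},{"kind":"EXTRACT","reagent":"","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"INFUSE","pump":1,"reagent":"PBS 1X","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"WAIT","reagent":"","duration":10,"repeat_n":1,"message":"","delay":15},{"kind":"EXTRACT","reagent":"","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"INFUSE","pump":1,"reagent":"PBS 1X","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"WAIT","reagent":"","duration":10,"repeat_n":1,"message":"","delay":15},{"kind":"EXTRACT","reagent":"","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"INFUSE","pump":1,"reagent":"PBS 1X","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"WAIT","reagent":"","duration":10,"repeat_n":1,"message":"","delay":15},{"kind":"EXTRACT","reagent":"","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"INFUSE","pump":2,"reagent":"BSA 5% + Triton-X 0.05%","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"WAIT","reagent":"","duration":30,"repeat_n":1,"message":"","delay":15},{"kind":"EXTRACT","reagent":"","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"INFUSE","pump":3,"reagent":"phalloidin-AF647 + DAPI","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"WAIT","reagent":"","duration":60,"repeat_n":1,"message":"","delay":15},{"kind":"EXTRACT","reagent":"","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"INFUSE","pump":1,"reagent":"PBS 1X","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"WAIT","reagent":"","duration":10,"repeat_n":1,"message":"","delay":15},{"kind":"EXTRACT","reagent":"","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"INFUSE","pump":1,"reagent":"PBS 1X","volume":500,"rate":6000,"repeat_n":1,"message":"","delay":15},{"kind":"WAIT","reagent":"","duration":10,"repeat_n":1,"message":"","delay":15},{"kind":"NOTIFY","reagent":"","repeat_n":1,"message":"staining complete","delay":15}]}
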