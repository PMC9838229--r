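# Sensory-motor substages 1-2: the grasping reflex. Two sensors converge
# (conjunction) to signal that an object and a hand are perceived in the
# same visual field X; a short-term potentiation opens the path from the
# object sensor to the grasp effector for the current cycle.
circuit grasp
stream vis
node sensor vis s_vobj view(obj(P,X))
node sensor vis s_vhand view(hand(X))
node effector vis grasp grasp(obj(P,X))
edge conj s_vobj grasp w=0 plasticity=stp
edge conj s_vhand grasp w=1
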